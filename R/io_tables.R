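#' Read a site table
#'
#' Parses the CSV site table used throughout the pipeline. Expected
#' columns: `site_id`, `designations` (tokens from `{SPA, SCI}` joined
#' with `|`), coordinates (`x_km`/`y_km` for planar kilometres or
#' `lon`/`lat` for degrees), `zero_distance_partners` (`|`-separated site
#' ids, empty when none), `missing_landuse`, `on_mainland`, and an
#' optional `boundary` column holding polygon vertices as
#' `"x1 y1;x2 y2;..."`.
#'
#' Overlapping SPA/SCI designations are modelled as two distinct site
#' records declared as zero-distance partners of each other; partnership
#' must be symmetric and is validated here.
#'
#' @param path path to a CSV file with a header row.
#' @return A `data.frame` of site records (one row per site) with an
#'   attribute `coord_mode` equal to `"planar"` or `"lonlat"`.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("site_id", "designations", "zero_distance_partners",
                "missing_landuse", "on_mainland")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("site table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (all(c("x_km", "y_km") %in% names(df))) {
    coord_mode <- "planar"
    df$x_km <- as.numeric(df$x_km)
    df$y_km <- as.numeric(df$y_km)
  } else if (all(c("lon", "lat") %in% names(df))) {
    coord_mode <- "lonlat"
    df$lon <- as.numeric(df$lon)
    df$lat <- as.numeric(df$lat)
  } else {
    stop("site table must provide x_km/y_km or lon/lat coordinates")
  }
  df$missing_landuse <- as.logical(df$missing_landuse)
  df$on_mainland <- as.logical(df$on_mainland)
  validate_sites(df)
  attr(df, "coord_mode") <- coord_mode
  df
}

validate_sites <- function(df) {
  dup <- unique(df$site_id[duplicated(df$site_id)])
  if (length(dup) > 0) {
    stop("duplicate site_id: ", paste(dup, collapse = ", "))
  }
  toks <- strsplit(df$designations, "|", fixed = TRUE)
  bad <- vapply(toks, function(t) {
    length(t) == 0 || any(!t %in% c("SPA", "SCI"))
  }, TRUE)
  if (any(bad)) {
    stop("unknown designation token in sites: ",
         paste(df$site_id[bad], collapse = ", "))
  }
  plist <- partner_list(df)
  for (i in seq_len(nrow(df))) {
    for (p in plist[[i]]) {
      j <- match(p, df$site_id)
      if (is.na(j)) {
        stop("site ", df$site_id[i], " lists unknown partner ", p)
      }
      if (!(df$site_id[i] %in% plist[[j]])) {
        stop("asymmetric zero-distance partnership: ", df$site_id[i],
             " lists ", p, " but not vice versa")
      }
    }
  }
  invisible(df)
}

partner_list <- function(sites) {
  lapply(strsplit(sites$zero_distance_partners, "|", fixed = TRUE),
         function(t) t[nzchar(t)])
}

#' Write a site table
#' @param sites site `data.frame` as returned by [read_site_table] or
#'   [generate_landscape].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a composition table
#'
#' The composition table carries one row per (site, dataset, code)
#' observation with a patch/occurrence `count` and a surface `area_ha`.
#' `dataset` must be one of `species`, `habitat`, `landuse`; species rows
#' record presence only (`count` 1, `area_ha` 0 permitted).
#'
#' @param path path to a CSV file with a header row.
#' @return A `data.frame` with columns `site_id`, `dataset`, `code`,
#'   `count`, `area_ha`.
#' @export
read_composition_table <- function(path) {
  if (!file.exists(path)) stop("composition table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(site_id = "character",
                                       code = "character"))
  required <- c("site_id", "dataset", "code", "count", "area_ha")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("composition table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  validate_compositions(df)
  df
}

validate_compositions <- function(df) {
  bad <- !df$dataset %in% c("species", "habitat", "landuse")
  if (any(bad)) {
    stop("unknown dataset token: ",
         paste(unique(df$dataset[bad]), collapse = ", "))
  }
  if (any(df$count < 1 | df$count != as.integer(df$count))) {
    stop("composition counts must be integers >= 1")
  }
  if (any(df$area_ha < 0)) stop("composition areas must be >= 0")
  key <- paste(df$site_id, df$dataset, df$code, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (site_id, dataset, code) rows in composition table")
  }
  invisible(df)
}

#' Write a composition table
#' @param compositions composition `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(compositions, path) {
  utils::write.csv(compositions, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Filter sites for analysis inclusion
#'
#' Reproduces the case-study site filter: optionally drop sites with
#' missing land-use composition and sites off the mainland (minor
#' islands), so that graph conclusions remain applicable to land
#' animals. Excluded ids are reported via `message()`.
#'
#' @param sites site `data.frame`.
#' @param require_landuse drop sites flagged `missing_landuse`.
#' @param mainland_only drop sites with `on_mainland = FALSE`.
#' @return The filtered site `data.frame` (attributes preserved).
#' @export
filter_sites <- function(sites, require_landuse = TRUE,
                         mainland_only = TRUE) {
  keep <- rep(TRUE, nrow(sites))
  if (mainland_only) {
    drop <- !sites$on_mainland
    if (any(drop)) {
      message("excluding off-mainland sites: ",
              paste(sites$site_id[drop], collapse = ", "))
    }
    keep <- keep & !drop
  }
  if (require_landuse) {
    drop <- keep & sites$missing_landuse
    if (any(drop)) {
      message("excluding sites with missing land-use data: ",
              paste(sites$site_id[drop], collapse = ", "))
    }
    keep <- keep & !drop
  }
  if (!any(keep)) warning("no sites remain after filtering")
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coord_mode") <- attr(sites, "coord_mode")
  out
}

# --- distances ---------------------------------------------------------

EARTH_RADIUS_KM <- 6371.0088

great_circle_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

parse_boundary <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  pts <- strsplit(trimws(strsplit(s, ";", fixed = TRUE)[[1]]), "[ ]+")
  m <- do.call(rbind, lapply(pts, as.numeric))
  colnames(m) <- c("x", "y")
  m
}

point_segment_dist <- function(px, py, ax, ay, bx, by) {
  abx <- bx - ax; aby <- by - ay
  len2 <- abx^2 + aby^2
  t <- if (len2 == 0) 0 else ((px - ax) * abx + (py - ay) * aby) / len2
  t <- min(1, max(0, t))
  sqrt((px - (ax + t * abx))^2 + (py - (ay + t * aby))^2)
}

# minimum distance from any vertex of one polygon to any boundary
# segment of the other, in both directions (closed rings)
polygon_min_dist <- function(P, Q) {
  segs <- function(M) {
    n <- nrow(M)
    cbind(M, M[c(2:n, 1), , drop = FALSE])
  }
  best <- Inf
  for (pair in list(list(P, Q), list(Q, P))) {
    S <- segs(pair[[2]])
    for (i in seq_len(nrow(pair[[1]]))) {
      p <- pair[[1]][i, ]
      d <- mapply(point_segment_dist, p[1], p[2],
                  S[, 1], S[, 2], S[, 3], S[, 4])
      best <- min(best, d)
    }
  }
  best
}

#' Compute the inter-site distance matrix
#'
#' Distances are in kilometres. Three modes are supported: `planar`
#' (Euclidean on `x_km`/`y_km` coordinates), `geodesic` (great-circle on
#' `lon`/`lat` using a spherical Earth of radius 6371.0088 km), and
#' `boundary` (minimum vertex-to-segment distance between the sites'
#' boundary polygons on planar coordinates). Declared zero-distance
#' partner pairs — the representation of overlapping SPA/SCI boundaries —
#' are forced to distance 0 after computation, regardless of coordinates.
#'
#' @param sites site `data.frame`.
#' @param mode `"planar"`, `"geodesic"` or `"boundary"`.
#' @return A symmetric numeric matrix with zero diagonal, dimnames =
#'   site ids.
#' @export
compute_distances <- function(sites,
                              mode = c("planar", "geodesic", "boundary")) {
  mode <- match.arg(mode)
  n <- nrow(sites)
  ids <- sites$site_id
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (mode == "planar") {
    D[] <- as.matrix(stats::dist(cbind(sites$x_km, sites$y_km)))
  } else if (mode == "geodesic") {
    if (!all(c("lon", "lat") %in% names(sites))) {
      stop("geodesic mode requires lon/lat columns")
    }
    for (i in seq_len(n)) {
      D[i, ] <- great_circle_km(sites$lon[i], sites$lat[i],
                                sites$lon, sites$lat)
    }
    diag(D) <- 0
    D <- (D + t(D)) / 2  # symmetrize away rounding noise
  } else {
    if (!"boundary" %in% names(sites)) {
      stop("boundary mode requires a 'boundary' column of polygons")
    }
    polys <- lapply(sites$boundary, parse_boundary)
    if (any(vapply(polys, is.null, TRUE))) {
      stop("boundary mode requires a polygon for every site")
    }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j > i) D[i, j] <- polygon_min_dist(polys[[i]], polys[[j]])
      }
    }
    D <- D + t(D)
  }
  # zero-distance override for overlapping designation pairs
  plist <- partner_list(sites)
  for (i in seq_len(n)) {
    js <- match(plist[[i]], ids)
    js <- js[!is.na(js)]
    D[i, js] <- 0
    D[js, i] <- 0
  }
  D
}

# --- graph I/O ---------------------------------------------------------

#' Write a graph to GraphML or an edge-list CSV
#'
#' GraphML output preserves node attributes (pass a `data.frame` keyed by
#' `site_id`, e.g. designations or species occupancy marks) plus the
#' graph's `kind`; the edge-list CSV holds two columns `from`, `to` with
#' a header and loses attributes.
#'
#' @param g an [eco_graph].
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist_csv"`.
#' @param node_attrs optional `data.frame` with a `site_id` column and
#'   attribute columns to attach to vertices (GraphML only).
#' @return `path`, invisibly.
#' @export
write_eco_graph <- function(g, path, format = c("graphml", "edgelist_csv"),
                            node_attrs = NULL) {
  stopifnot(inherits(g, "eco_graph"))
  format <- match.arg(format)
  if (format == "edgelist_csv") {
    utils::write.csv(g$edges, path, row.names = FALSE, quote = TRUE)
    return(invisible(path))
  }
  ig <- as_igraph(g)
  ig <- igraph::set_graph_attr(ig, "kind", g$kind)
  if (!is.null(node_attrs)) {
    idx <- match(g$nodes, node_attrs$site_id)
    for (col in setdiff(names(node_attrs), "site_id")) {
      ig <- igraph::set_vertex_attr(ig, col, value = node_attrs[[col]][idx])
    }
  }
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file back into an eco_graph
#' @param path GraphML file written by [write_eco_graph].
#' @return An [eco_graph]; vertex attributes are attached as a
#'   `node_attrs` attribute.
#' @export
read_eco_graph <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::vertex_attr(ig, "name")
  el <- igraph::as_edgelist(ig, names = TRUE)
  kind <- tryCatch(igraph::graph_attr(ig, "kind"),
                   error = function(e) "raw_distance")
  if (is.null(kind) || is.na(kind)) kind <- "raw_distance"
  g <- eco_graph(nodes, el, kind)
  va <- setdiff(igraph::vertex_attr_names(ig), "name")
  if (length(va) > 0) {
    attrs <- data.frame(site_id = nodes, stringsAsFactors = FALSE)
    for (a in va) attrs[[a]] <- igraph::vertex_attr(ig, a)
    attr(g, "node_attrs") <- attrs
  }
  g
}
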