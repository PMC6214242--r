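#' Ecological site graph
#'
#' Lightweight container for the undirected simple graphs handled by the
#' package: a node set of site identifiers, an edge set of unordered site
#' pairs, a construction `kind` and the construction parameters. Edges are
#' stored canonically with `from < to` (lexicographic), so `(a, b)` and
#' `(b, a)` denote the same edge and duplicates or self-loops cannot be
#' represented.
#'
#' @param nodes character vector of unique site ids.
#' @param edges two-column `data.frame` (or matrix) of site id pairs; may
#'   have zero rows.
#' @param kind one of `"raw_distance"`, `"single_species"`,
#'   `"full_single_species"`, `"similarity"`.
#' @param params named list of construction parameters
#'   (e.g. `distance_threshold_km`, `species_code`, `measure`, `dataset`,
#'   `mode`, `similarity_threshold`).
#'
#' @return An object of class `eco_graph` with elements `nodes`, `edges`
#'   (data.frame with columns `from`, `to`), `kind` and `params`.
#' @export
eco_graph <- function(nodes, edges, kind, params = list()) {
  kinds <- c("raw_distance", "single_species", "full_single_species",
             "similarity")
  kind <- match.arg(kind, kinds)
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop("duplicate node ids: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    if (ncol(edges) < 2) stop("edges must have two columns")
    from <- as.character(edges[[1]])
    to <- as.character(edges[[2]])
    if (any(from == to)) stop("self-loops are not permitted")
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
    unknown <- setdiff(unique(c(from, to)), nodes)
    if (length(unknown) > 0) {
      stop("edge endpoints not in node set: ",
           paste(unknown, collapse = ", "))
    }
    keep <- !duplicated(paste(from, to, sep = "\r"))
    edges <- data.frame(from = from[keep], to = to[keep],
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, kind = kind,
                 params = params),
            class = "eco_graph")
}

#' Number of edges in an ecological graph
#' @param g an [eco_graph] object.
#' @return Integer edge count.
#' @export
n_edges <- function(g) {
  stopifnot(inherits(g, "eco_graph"))
  nrow(g$edges)
}

# Canonical "from\rto" keys; set operations on edges go through these.
edge_keys <- function(g) {
  if (nrow(g$edges) == 0) return(character(0))
  paste(g$edges$from, g$edges$to, sep = "\r")
}

keys_to_edges <- function(keys) {
  if (length(keys) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(from = vapply(parts, `[`, "", 1L),
             to = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Convert an ecological graph to an igraph object
#'
#' Nodes become vertices named by site id; the result is undirected and
#' simple by construction.
#'
#' @param g an [eco_graph] object.
#' @return An [igraph::igraph] graph.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "eco_graph"))
  ig <- igraph::make_empty_graph(n = 0, directed = FALSE)
  ig <- igraph::add_vertices(ig, length(g$nodes), name = g$nodes)
  if (nrow(g$edges) > 0) {
    ig <- igraph::add_edges(ig, rbind(g$edges$from, g$edges$to))
  }
  ig
}

#' @export
print.eco_graph <- function(x, ...) {
  cat(sprintf("<eco_graph kind=%s | %d nodes, %d edges>\n",
              x$kind, length(x$nodes), nrow(x$edges)))
  if (length(x$params) > 0) {
    pv <- vapply(x$params, function(p) paste(format(p), collapse = ","), "")
    cat("  params: ", paste(names(pv), pv, sep = "=", collapse = "; "),
        "\n", sep = "")
  }
  invisible(x)
}
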