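#' Truncate a CORINE land-cover code to level 3
#'
#' CLC codes are hierarchical; the third level (three digits, e.g. `311`
#' for broad-leaved forest) is the reference level for land-use vectors,
#' as deeper levels are rarely available consistently. Accepts dotted
#' (`"3.1.1"`) or plain (`"311"`, `"3111"`) spellings.
#'
#' @param code character vector of CLC-style codes.
#' @return The 3-digit level-3 prefix of each code.
#' @export
clc_level3 <- function(code) {
  digits <- gsub("[^0-9]", "", code)
  bad <- nchar(digits) < 3
  if (any(bad)) {
    stop("CLC code with fewer than 3 digits: ",
         paste(unique(code[bad]), collapse = ", "))
  }
  substr(digits, 1, 3)
}

#' Build per-site attribute vectors for one dataset
#'
#' Each included site becomes a row over the universe of codes observed
#' in the dataset across included sites (set semantics: the universe is
#' sorted and independent of site order). Land-use codes are first
#' truncated to CLC level 3, with counts and areas aggregated over the
#' truncation. Three modes are available:
#' \describe{
#'   \item{binary}{1 iff the (site, code) pair is present;}
#'   \item{count}{summed occurrence/patch counts;}
#'   \item{area}{summed surface area in hectares.}
#' }
#' Species data carries presence only, so `dataset = "species"` permits
#' `mode = "binary"` alone. Sites with no rows for the dataset are
#' retained with an all-zero vector so every graph shares one node set.
#'
#' @param compositions composition `data.frame`
#'   (see [read_composition_table]).
#' @param sites site `data.frame`; defines the row set and order.
#' @param dataset `"species"`, `"habitat"` or `"landuse"`.
#' @param mode `"binary"`, `"count"` or `"area"`.
#' @return A `site_vector_set`: list with `dataset`, `mode`, `codes`
#'   (ordered universe) and `matrix` (sites x codes, rownames = site ids).
#' @export
build_vector_set <- function(compositions, sites,
                             dataset = c("species", "habitat", "landuse"),
                             mode = c("binary", "count", "area")) {
  dataset <- match.arg(dataset)
  mode <- match.arg(mode)
  if (dataset == "species" && mode != "binary") {
    stop("species vectors are binary only; population-abundance data ",
         "is not modelled")
  }
  rows <- compositions[compositions$dataset == dataset, , drop = FALSE]
  rows <- rows[rows$site_id %in% sites$site_id, , drop = FALSE]
  if (dataset == "landuse" && nrow(rows) > 0) {
    rows$code <- clc_level3(rows$code)
  }
  codes <- sort(unique(rows$code))
  ids <- sites$site_id
  M <- matrix(0, nrow = length(ids), ncol = length(codes),
              dimnames = list(ids, codes))
  if (nrow(rows) > 0) {
    i <- match(rows$site_id, ids)
    j <- match(rows$code, codes)
    val <- switch(mode,
                  binary = rep(1, nrow(rows)),
                  count = rows$count,
                  area = rows$area_ha)
    for (k in seq_len(nrow(rows))) {
      M[i[k], j[k]] <- M[i[k], j[k]] + val[k]
    }
    if (mode == "binary") M[M > 0] <- 1
    if (mode == "area") {
      present <- tapply(rep(TRUE, nrow(rows)), rows$site_id, any)
      zero_area <- rowSums(M)[names(present)] == 0
      if (any(zero_area)) {
        stop("area mode: sites with composition rows but zero total ",
             "area: ", paste(names(present)[zero_area], collapse = ", "))
      }
    }
  }
  structure(list(dataset = dataset, mode = mode, codes = codes,
                 matrix = M),
            class = "site_vector_set")
}

#' @export
print.site_vector_set <- function(x, ...) {
  cat(sprintf("<site_vector_set %s/%s | %d sites x %d codes>\n",
              x$dataset, x$mode, nrow(x$matrix), length(x$codes)))
  invisible(x)
}

#' Export a vector set as a wide CSV (site x code) for inspection
#' @param vs a `site_vector_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_vector_set <- function(vs, path) {
  df <- data.frame(site_id = rownames(vs$matrix), vs$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
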