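#' Jaccard coefficient of two binary vectors
#'
#' With `f11` the attributes set in both vectors, `f10` those set only in
#' the first and `f01` only in the second, the coefficient is
#' `f11 / (f01 + f10 + f11)`: 0 for disjoint supports, 1 for identical
#' non-empty vectors. Two all-zero vectors have no shared information;
#' their similarity is defined as 0 and a warning is raised, so sparse
#' data cannot silently create links.
#'
#' @param u,v binary (0/1) numeric vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  if (any(!(u %in% c(0, 1))) || any(!(v %in% c(0, 1)))) {
    stop("jaccard requires binary (0/1) vectors")
  }
  f11 <- sum(u == 1 & v == 1)
  denom <- sum(u == 1 | v == 1)  # f01 + f10 + f11
  if (denom == 0) {
    warning("jaccard of two empty vectors: defined as 0")
    return(0)
  }
  f11 / denom
}

#' Cosine similarity of two non-negative vectors
#'
#' The cosine of the angle between the vectors, `x . y / (||x|| ||y||)`,
#' lying in `[0, 1]` for non-negative inputs. Undefined for a
#' zero-magnitude vector: the definition requires non-zero magnitude, so
#' such pairs raise an error here and are recorded as no-edge by the
#' pairwise wrapper.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
cosine <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop("cosine similarity undefined for zero-magnitude vector")
  }
  min(1, sum(x * y) / (nx * ny))
}

#' Pairwise site similarity matrix
#'
#' Computes the full symmetric matrix of Jaccard or cosine similarities
#' over the rows of a [build_vector_set] result. Jaccard requires binary
#' mode; cosine accepts count, area or binary vectors. Pairs with an
#' undefined similarity (a zero-magnitude vector under cosine, including
#' its diagonal entry) are stored as `NA` and treated as below any
#' threshold by graph construction. Empty-vs-empty Jaccard pairs score 0;
#' the number of such pairs is reported once as a warning.
#'
#' @param vs a `site_vector_set`.
#' @param measure `"jaccard"` or `"cosine"`.
#' @return A symmetric numeric matrix (dimnames = site ids) of class
#'   `similarity_matrix`, with attributes `measure`, `dataset`, `mode`.
#' @export
pairwise_similarity <- function(vs, measure = c("jaccard", "cosine")) {
  measure <- match.arg(measure)
  stopifnot(inherits(vs, "site_vector_set"))
  if (measure == "jaccard" && vs$mode != "binary") {
    stop("jaccard requires binary vectors; got mode '", vs$mode, "'")
  }
  M <- vs$matrix
  n <- nrow(M)
  if (measure == "jaccard") {
    inter <- M %*% t(M)                       # f11
    sz <- rowSums(M)
    uni <- outer(sz, sz, `+`) - inter         # f01 + f10 + f11
    S <- ifelse(uni == 0, 0, inter / uni)
    empty_pairs <- sum(uni[upper.tri(uni)] == 0)
    if (empty_pairs > 0) {
      warning(empty_pairs,
              " empty-vs-empty vector pair(s): jaccard defined as 0")
    }
    diag(S) <- ifelse(sz > 0, 1, 0)
  } else {
    nrm <- sqrt(rowSums(M^2))
    S <- (M %*% t(M)) / outer(nrm, nrm)
    S[nrm == 0, ] <- NA_real_
    S[, nrm == 0] <- NA_real_
    S <- pmin(S, 1)
    diag(S) <- ifelse(nrm > 0, 1, NA_real_)
  }
  S <- (S + t(S)) / 2  # exact symmetry despite float noise
  dimnames(S) <- list(rownames(M), rownames(M))
  structure(S, class = c("similarity_matrix", "matrix"),
            measure = measure, dataset = vs$dataset, mode = vs$mode)
}

#' Export a similarity matrix as a square CSV
#' @param S a `similarity_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(S, path) {
  df <- data.frame(site_id = rownames(S), unclass(S),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
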