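# Graph construction: the four graph families of the analysis.
# All constructors share one primitive that enumerates site pairs within
# the geographical distance threshold, so nestedness of edge sets holds
# by construction.

threshold_pairs <- function(D, threshold_km) {
  ids <- rownames(D)
  idx <- which(upper.tri(D) & D <= threshold_km, arr.ind = TRUE)
  data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Build the raw-distance graph
#'
#' Links every pair of sites whose distance is within the threshold
#' (inclusive, `d <= threshold_km`). Declared zero-distance partner
#' pairs have distance 0 in the matrix and are therefore always linked.
#' The raw-distance edge count is the `n` of the normalized hit rate.
#'
#' @param sites site `data.frame`.
#' @param D distance matrix from [compute_distances].
#' @param threshold_km geographical distance threshold in km
#'   (default 30, the case-study setting).
#' @return An [eco_graph] of kind `"raw_distance"`.
#' @export
build_raw_distance <- function(sites, D, threshold_km = 30) {
  stopifnot(threshold_km >= 0)
  D <- D[sites$site_id, sites$site_id, drop = FALSE]
  eco_graph(sites$site_id, threshold_pairs(D, threshold_km),
            kind = "raw_distance",
            params = list(distance_threshold_km = threshold_km))
}

#' Build a single-species graph
#'
#' Edges link pairs of sites within the distance threshold where the
#' target species is reported in both. With `full = FALSE` the node set
#' is the occupied sites only (the single-species graph whose connected
#' components feed the candidate finder); with `full = TRUE` all sites
#' are kept as nodes with the same edges (the full single-species graph
#' used for comparison against similarity-based graphs).
#'
#' @param occupancy character vector of occupied site ids, or a list
#'   with elements `species_code` and `occupied`.
#' @param sites site `data.frame` (the node universe).
#' @param D distance matrix.
#' @param threshold_km distance threshold in km.
#' @param full keep the full node set?
#' @param species_code optional species label stored in params.
#' @return An [eco_graph] of kind `"single_species"` or
#'   `"full_single_species"`.
#' @export
build_single_species <- function(occupancy, sites, D, threshold_km = 30,
                                 full = FALSE, species_code = NULL) {
  if (is.list(occupancy) && !is.null(occupancy$occupied)) {
    species_code <- species_code %||% occupancy$species_code
    occupancy <- occupancy$occupied
  }
  occupancy <- as.character(occupancy)
  unknown <- setdiff(occupancy, sites$site_id)
  if (length(unknown) > 0) {
    stop("occupied sites not in site table: ",
         paste(unknown, collapse = ", "))
  }
  D <- D[sites$site_id, sites$site_id, drop = FALSE]
  pairs <- threshold_pairs(D, threshold_km)
  keep <- pairs$from %in% occupancy & pairs$to %in% occupancy
  nodes <- if (full) sites$site_id else
    sites$site_id[sites$site_id %in% occupancy]
  eco_graph(nodes, pairs[keep, , drop = FALSE],
            kind = if (full) "full_single_species" else "single_species",
            params = list(distance_threshold_km = threshold_km,
                          species_code = species_code))
}

#' Build a similarity-based graph
#'
#' Links pairs of sites that are both within the distance threshold and
#' at least `min_sim` similar (inclusive, `s >= min_sim`, exact double
#' comparison). This is equivalent to removing from the raw-distance
#' graph the edges whose similarity falls below the minimum score. Pairs
#' whose similarity is undefined (`NA`, e.g. a zero-magnitude vector
#' under cosine) are never linked.
#'
#' @param sites site `data.frame`.
#' @param D distance matrix.
#' @param S similarity matrix from [pairwise_similarity].
#' @param threshold_km distance threshold in km.
#' @param min_sim minimum similarity score in `[0, 1]` (default 0.5,
#'   the common reference threshold of the analysis).
#' @return An [eco_graph] of kind `"similarity"` whose edge set is a
#'   subset of the raw-distance edge set.
#' @export
build_similarity_graph <- function(sites, D, S, threshold_km = 30,
                                   min_sim = 0.5) {
  if (min_sim < 0 || min_sim > 1) stop("min_sim must be in [0, 1]")
  ids <- sites$site_id
  D <- D[ids, ids, drop = FALSE]
  S <- S[ids, ids, drop = FALSE]
  pairs <- threshold_pairs(D, threshold_km)
  s <- S[cbind(pairs$from, pairs$to)]
  keep <- !is.na(s) & s >= min_sim
  eco_graph(ids, pairs[keep, , drop = FALSE],
            kind = "similarity",
            params = list(distance_threshold_km = threshold_km,
                          similarity_threshold = min_sim,
                          measure = attr(S, "measure"),
                          dataset = attr(S, "dataset"),
                          mode = attr(S, "mode")))
}

#' Edge counts along a similarity-threshold sweep
#'
#' Counts the edges of the similarity-based graph at each requested
#' minimum-similarity level, the conventional layout of edge-count
#' sweeps. Level 0 recovers the raw-distance edge count (up to pairs
#' with undefined similarity); counts are non-increasing in the level.
#'
#' @param sites,D,S,threshold_km as in [build_similarity_graph].
#' @param sim_levels numeric vector of levels in `[0, 1]`
#'   (default `seq(0, 0.9, by = 0.1)`).
#' @return A `data.frame` with columns `min_sim`, `n_edges`,
#'   `removed_pct` (percentage of raw-distance edges removed).
#' @export
edge_count_sweep <- function(sites, D, S, threshold_km = 30,
                             sim_levels = seq(0, 0.9, by = 0.1)) {
  if (any(sim_levels < 0 | sim_levels > 1)) {
    stop("sweep levels must lie in [0, 1]")
  }
  raw <- n_edges(build_raw_distance(sites, D, threshold_km))
  counts <- vapply(sim_levels, function(lv) {
    n_edges(build_similarity_graph(sites, D, S, threshold_km, lv))
  }, integer(1))
  data.frame(min_sim = sim_levels, n_edges = counts,
             removed_pct = removal_percentages(counts, raw))
}

#' Percentage of raw-distance edges removed at a similarity level
#'
#' Given similarity-graph edge counts and the raw-distance edge count
#' `n`, returns `100 * (1 - count / n)` — the quantity used to judge how
#' strong a similarity threshold is.
#'
#' @param edge_counts integer vector of similarity-graph edge counts.
#' @param n_raw raw-distance graph edge count (positive).
#' @return Numeric vector of removal percentages.
#' @export
removal_percentages <- function(edge_counts, n_raw) {
  stopifnot(n_raw > 0)
  100 * (1 - edge_counts / n_raw)
}
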