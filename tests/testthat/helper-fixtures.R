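# in-code fixtures shared across test files

make_sites <- function(ids, x, y, designations = "SPA",
                       partners = "", missing_landuse = FALSE,
                       on_mainland = TRUE) {
  df <- data.frame(site_id = ids,
                   designations = rep_len(designations, length(ids)),
                   x_km = x, y_km = y,
                   zero_distance_partners = rep_len(partners, length(ids)),
                   missing_landuse = rep_len(missing_landuse, length(ids)),
                   on_mainland = rep_len(on_mainland, length(ids)),
                   stringsAsFactors = FALSE)
  attr(df, "coord_mode") <- "planar"
  df
}

comp_row <- function(site_id, dataset, code, count = 1L, area_ha = 0) {
  data.frame(site_id = site_id, dataset = dataset, code = code,
             count = as.integer(count), area_ha = area_ha,
             stringsAsFactors = FALSE)
}

# a small graph whose species edge set has a chosen size and overlap
# with a second graph's edge set, on a disjoint-pairs node universe
make_overlap_graphs <- function(m, h, threshold = 30) {
  stopifnot(h <= m)
  nodes <- sprintf("n%03d", seq_len(2 * m))
  a <- nodes[seq(1, 2 * m, by = 2)]
  b <- nodes[seq(2, 2 * m, by = 2)]
  sp <- eco_graph(nodes, data.frame(from = a, to = b),
                  kind = "full_single_species",
                  params = list(distance_threshold_km = threshold))
  sim <- eco_graph(nodes,
                   data.frame(from = a[seq_len(h)], to = b[seq_len(h)]),
                   kind = "similarity",
                   params = list(distance_threshold_km = threshold))
  list(species = sp, sim = sim)
}

# random undirected simple graph as eco_graph, n nodes
random_eco_graph <- function(n, p) {
  nodes <- letters[seq_len(n)]
  A <- matrix(0L, n, n)
  if (n > 1) {
    up <- which(upper.tri(A))
    A[up] <- stats::rbinom(length(up), 1, p)
    A <- A + t(A)
  }
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  eco_graph(nodes, data.frame(from = nodes[idx[, 1]],
                              to = nodes[idx[, 2]]),
            kind = "raw_distance", params = list())
  }

adjacency_of <- function(g) {
  n <- length(g$nodes)
  A <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges) > 0) {
    A[cbind(g$edges$from, g$edges$to)] <- 1
    A[cbind(g$edges$to, g$edges$from)] <- 1
  }
  A
}
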