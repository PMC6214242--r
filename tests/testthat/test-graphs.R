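# shared small landscape for graph construction tests
graph_fixture <- function(seed = 21, n = 40) {
  b <- generate_landscape(landscape_config(n_sites = n, seed = seed))
  sites <- filter_sites(b$sites, TRUE, TRUE)
  list(bundle = b, sites = sites,
       D = compute_distances(sites, "planar"))
}

test_that("raw-distance graphs link all pairs within the threshold", {
  sites <- make_sites(c("A", "B", "C"), x = c(0, 10, 30), y = 0)
  D <- compute_distances(sites, "planar")  # d = 10, 20, 30... -> use y
  # distances: A-B 10, B-C 20, A-C 30; threshold 30 inclusive keeps all
  g <- build_raw_distance(sites, D, 25)
  expect_equal(n_edges(g), 2)
  g30 <- build_raw_distance(sites, D, 30)
  expect_equal(n_edges(g30), 3)  # the threshold comparison is inclusive
  # threshold zero: only declared partner pairs remain linked
  sites2 <- make_sites(c("A", "B", "P"), x = c(0, 10, 5), y = 0,
                       partners = c("P", "", "A"))
  g0 <- build_raw_distance(sites2, compute_distances(sites2, "planar"), 0)
  expect_equal(g0$edges, data.frame(from = "A", to = "P"))
})

test_that("raw-distance edge counts match brute-force pair enumeration", {
  fx <- graph_fixture(seed = 31, n = 104)
  g <- build_raw_distance(fx$sites, fx$D, 30)
  brute <- 0
  ids <- fx$sites$site_id
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j > i && fx$D[i, j] <= 30) brute <- brute + 1
  }
  expect_equal(n_edges(g), brute)
})

test_that("single-species graphs restrict edges to co-occupied pairs", {
  sites <- make_sites(c("A", "B", "C"), x = c(0, 10, 100), y = 0)
  D <- compute_distances(sites, "planar")
  g <- build_single_species(c("A", "B"), sites, D, 30,
                            species_code = "1367")
  expect_equal(n_edges(g), 1)
  expect_identical(g$nodes, c("A", "B"))
  gf <- build_single_species(c("A", "B"), sites, D, 30, full = TRUE)
  expect_identical(gf$nodes, sites$site_id)
  expect_identical(gf$edges, g$edges)
  expect_error(build_single_species(c("A", "Z"), sites, D, 30), "Z")

  fx <- graph_fixture(seed = 8)
  occ <- species_occupancy(fx$bundle$compositions)
  occ <- lapply(occ, intersect, fx$sites$site_id)
  occ <- occ[vapply(occ, length, 1L) >= 2][1:5]
  raw_keys <- with(build_raw_distance(fx$sites, fx$D, 30)$edges,
                   paste(from, to, sep = "|"))
  for (code in names(occ)) {
    sp <- build_single_species(occ[[code]], fx$sites, fx$D, 30,
                               full = TRUE, species_code = code)
    keys <- with(sp$edges, paste(from, to, sep = "|"))
    # subset oracle: exactly the raw edges with both endpoints occupied
    parts <- strsplit(raw_keys, "|", fixed = TRUE)
    expected <- raw_keys[vapply(parts, function(p) {
      all(p %in% occ[[code]])
    }, TRUE)]
    expect_setequal(keys, expected)
  }
})

test_that("similarity graphs equal raw-distance graphs filtered by score", {
  fx <- graph_fixture(seed = 13)
  vs <- build_vector_set(fx$bundle$compositions, fx$sites, "habitat",
                         "binary")
  S <- pairwise_similarity(vs, "jaccard")
  raw <- build_raw_distance(fx$sites, fx$D, 30)
  for (min_sim in c(0, 0.5, 1)) {
    g <- build_similarity_graph(fx$sites, fx$D, S, 30, min_sim)
    # dual construction: remove raw edges below the score
    s <- S[cbind(raw$edges$from, raw$edges$to)]
    kept <- raw$edges[!is.na(s) & s >= min_sim, ]
    rownames(kept) <- NULL
    expect_identical(g$edges, kept)
  }
  g0 <- build_similarity_graph(fx$sites, fx$D, S, 30, 0)
  expect_lte(n_edges(g0), n_edges(raw))
  expect_error(build_similarity_graph(fx$sites, fx$D, S, 30, 1.5),
               "min_sim")
})

test_that("edge counts are nested and non-increasing along the sweep", {
  fx <- graph_fixture(seed = 17)
  vs <- build_vector_set(fx$bundle$compositions, fx$sites, "habitat",
                         "count")
  S <- pairwise_similarity(vs, "cosine")
  levels <- seq(0, 0.9, by = 0.1)
  sw <- edge_count_sweep(fx$sites, fx$D, S, 30, levels)
  expect_equal(nrow(sw), length(levels))
  expect_true(all(diff(sw$n_edges) <= 0))
  raw <- build_raw_distance(fx$sites, fx$D, 30)
  expect_equal(sw$n_edges[1], n_edges(raw))
  # per-level independent reconstruction matches the sweep
  for (k in seq_along(levels)) {
    g <- build_similarity_graph(fx$sites, fx$D, S, 30, levels[k])
    expect_equal(sw$n_edges[k], n_edges(g))
    expect_equal(sw$removed_pct[k],
                 100 * (1 - n_edges(g) / n_edges(raw)))
  }
  # nestedness of the edge sets themselves
  g5 <- build_similarity_graph(fx$sites, fx$D, S, 30, 0.5)
  g7 <- build_similarity_graph(fx$sites, fx$D, S, 30, 0.7)
  k5 <- with(g5$edges, paste(from, to))
  k7 <- with(g7$edges, paste(from, to))
  expect_true(all(k7 %in% k5))
})

test_that("graphs store each unordered pair once with no self-loops", {
  expect_error(eco_graph("A", data.frame(from = "A", to = "A"),
                         "raw_distance"), "self-loop")
  g <- eco_graph(c("B", "A"), data.frame(from = c("B", "A"),
                                         to = c("A", "B")),
                 "raw_distance")
  expect_equal(n_edges(g), 1)
  expect_identical(g$edges, data.frame(from = "A", to = "B"))
})
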