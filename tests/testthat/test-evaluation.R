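test_that("hit rates count species edges present in the similarity graph", {
  gs <- make_overlap_graphs(15, 8)
  hr <- hit_rate(gs$species, gs$sim)
  expect_equal(hr$m, 15)
  expect_equal(hr$h, 8)
  expect_equal(hr$rate, 8 / 15)

  contained <- make_overlap_graphs(6, 6)
  expect_equal(hit_rate(contained$species, contained$sim)$rate, 1)

  disjoint <- make_overlap_graphs(4, 0)
  expect_equal(hit_rate(disjoint$species, disjoint$sim)$rate, 0)

  empty_sp <- eco_graph(c("A", "B"), data.frame(),
                        "full_single_species",
                        params = list(distance_threshold_km = 30))
  expect_true(is.na(hit_rate(empty_sp, disjoint$sim)$rate))

  other_thr <- eco_graph(c("A", "B"), data.frame(), "similarity",
                         params = list(distance_threshold_km = 20))
  expect_error(hit_rate(empty_sp, other_thr), "threshold")
})

test_that("evaluation summaries satisfy the normalized-hit-rate identity", {
  rates <- c(0.5, 0.25, NA, 1)
  ev <- summarize_hit_rates(rates, E = 120, n = 700, label = "x")
  expect_equal(ev$R, mean(c(0.5, 0.25, 1)))  # undefined rates excluded
  expect_equal(ev$density, 120 / 700)
  expect_equal(ev$nhr * ev$density, ev$R, tolerance = 1e-12)
  # density one: the normalized hit rate is the average hit rate
  ev1 <- summarize_hit_rates(rates, E = 700, n = 700)
  expect_equal(ev1$nhr, ev1$R)
  # optional inclusion of undefined rates as zero
  ev0 <- summarize_hit_rates(rates, E = 120, n = 700,
                             include_undefined = TRUE)
  expect_equal(ev0$R, mean(c(0.5, 0.25, 0, 1)))
  expect_error(summarize_hit_rates(rates, E = 0, n = 700), "E = 0")
  expect_error(summarize_hit_rates(rates, E = 10, n = 0), "positive")
})

test_that("spearman uses mid-ranks and listwise deletion", {
  expect_equal(spearman(1:3, 1:3), 1)
  expect_equal(spearman(1:3, 3:1), -1)
  a <- c(1, 2, 2, 4); b <- c(1, 3, 2, 4)
  expect_equal(spearman(a, b), oracle_spearman(a, b))
  set.seed(77)
  for (rep in 1:25) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- x + sample(0:3, 12, replace = TRUE)
    expect_equal(spearman(x, y), oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
  withna <- c(1, NA, 3, 4, 5)
  expect_equal(spearman(withna, c(2, 9, 4, 1, 7)),
               oracle_spearman(withna, c(2, 9, 4, 1, 7)))
  expect_error(spearman(c(1, NA, 3), c(1, 2, NA)), "3 complete")
  expect_error(spearman(c(1, 1, 1), c(1, 2, 3)), "rank variance")
})

test_that("hit-rate and index correlation tables align by label and node", {
  rt <- data.frame(species_code = sprintf("%04d", 1:10),
                   m = rep(5L, 10),
                   rate_a = (1:10) / 10, rate_b = (1:10) / 10,
                   rate_c = (10:1) / 10)
  cc <- correlate_hit_rates(rt, list(c("a", "b"), c("a", "c")))
  expect_equal(cc$rho, c(1, -1))
  expect_error(correlate_hit_rates(rt, list(c("a", "zzz"))), "zzz")

  set.seed(12)
  g1 <- random_eco_graph(12, 0.4)
  g2 <- random_eco_graph(12, 0.4)
  tabs <- list(x = compute_indices(g1), y = compute_indices(g2))
  self <- correlate_indices(tabs, "degree", list(c("x", "x")))
  expect_equal(self$rho, 1)
  cross <- correlate_indices(tabs, "degree", list(c("x", "y")))
  expect_true(abs(cross$rho) <= 1)
  # node alignment is by id, not row order
  tabs$y2 <- tabs$x[rev(seq_len(nrow(tabs$x))), ]
  expect_equal(correlate_indices(tabs, "degree",
                                 list(c("x", "y2")))$rho, 1)
})

test_that("randomly permuted index columns decorrelate on large graphs", {
  b <- generate_landscape(landscape_config(n_sites = 104, seed = 14))
  sites <- filter_sites(b$sites, TRUE, TRUE)
  D <- compute_distances(sites, "planar")
  S <- pairwise_similarity(
    build_vector_set(b$compositions, sites, "habitat", "binary"),
    "jaccard")
  g <- build_similarity_graph(sites, D, S, 30, 0.4)
  ix <- compute_indices(g)
  rhos <- vapply(1:20, function(s) {
    set.seed(s)
    perm <- ix
    perm$degree <- sample(perm$degree)
    correlate_indices(list(a = ix, b = perm), "degree",
                      list(c("a", "b")))$rho
  }, 0)
  expect_lt(mean(abs(rhos)), 0.2)
})

test_that("candidate sets satisfy the four adjacency conditions exactly", {
  # minimal instance: one component {A, B}, similarity edge leaving it
  sites <- make_sites(c("A", "B", "C"), x = c(0, 10, 20), y = 0)
  D <- compute_distances(sites, "planar")
  sp <- build_single_species(c("A", "B"), sites, D, 30)
  sim <- eco_graph(c("A", "B", "C"),
                   data.frame(from = "B", to = "C"), "similarity",
                   params = list(distance_threshold_km = 30))
  cs <- find_candidates(sp, sim)
  expect_length(cs, 1)
  expect_identical(cs[[1]]$candidates,
                   data.frame(i = "B", j = "C"))
  # no similarity edge leaves the component: empty candidate set
  sim0 <- eco_graph(c("A", "B", "C"),
                    data.frame(from = "A", to = "B"), "similarity",
                    params = list(distance_threshold_km = 30))
  expect_equal(nrow(find_candidates(sp, sim0)[[1]]$candidates), 0)
})

test_that("candidate finder equals the exhaustive scan on random fixtures", {
  set.seed(314)
  for (rep in 1:40) {
    n <- sample(6:14, 1)
    b <- generate_landscape(landscape_config(
      n_sites = n, dual_designation_fraction = 0,
      missing_data_fraction = 0, seed = 1000 + rep))
    sites <- b$sites
    D <- compute_distances(sites, "planar")
    occ <- sample(sites$site_id, sample(2:(n - 1), 1))
    sp <- build_single_species(occ, sites, D, 30, species_code = "x")
    S <- pairwise_similarity(
      build_vector_set(b$compositions, sites, "habitat", "binary"),
      "jaccard")
    sim <- build_similarity_graph(sites, D, S, 30, runif(1, 0.1, 0.6))
    got <- find_candidates(sp, sim)
    want <- oracle_candidates(sp, sim)
    expect_equal(length(got), length(want))
    # match components by their node sets
    for (w in want) {
      gmatch <- Filter(function(g) setequal(g$component, w$component),
                       got)
      expect_length(gmatch, 1)
      expect_equal(gmatch[[1]]$candidates, w$candidates,
                   ignore_attr = TRUE)
    }
    # every emitted pair satisfies the four conditions
    for (g in got) {
      if (nrow(g$candidates) == 0) next
      expect_true(all(g$candidates$i %in% g$component))
      expect_true(all(!g$candidates$j %in% sp$nodes))
      keys <- paste(pmin(g$candidates$i, g$candidates$j),
                    pmax(g$candidates$i, g$candidates$j))
      expect_true(all(keys %in% paste(sim$edges$from, sim$edges$to)))
    }
  }
})

test_that("lowering the similarity threshold never lowers a hit rate", {
  b <- generate_landscape(landscape_config(n_sites = 50, seed = 23))
  sites <- filter_sites(b$sites, TRUE, TRUE)
  D <- compute_distances(sites, "planar")
  S <- pairwise_similarity(
    build_vector_set(b$compositions, sites, "habitat", "binary"),
    "jaccard")
  occ <- species_occupancy(b$compositions)
  occ <- occ[vapply(occ, length, 1L) >= 3][1:10]
  sp <- lapply(occ, function(o) {
    build_single_species(intersect(o, sites$site_id), sites, D, 30,
                         full = TRUE)
  })
  for (pair in list(c(0.3, 0.5), c(0.5, 0.7))) {
    glo <- build_similarity_graph(sites, D, S, 30, pair[1])
    ghi <- build_similarity_graph(sites, D, S, 30, pair[2])
    for (g in sp) {
      rlo <- hit_rate(g, glo)$rate
      rhi <- hit_rate(g, ghi)$rate
      if (!is.na(rlo) && !is.na(rhi)) expect_gte(rlo, rhi)
    }
  }
})
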