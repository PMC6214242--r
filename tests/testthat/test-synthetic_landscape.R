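test_that("configuration is validated with the offending field named", {
  expect_error(landscape_config(n_sites = 0), "n_sites")
  expect_error(landscape_config(dual_designation_fraction = 1.2),
               "dual_designation_fraction")
  expect_error(landscape_config(missing_data_fraction = -0.1),
               "missing_data_fraction")
  expect_error(landscape_config(habitat_species_coupling = -1),
               "habitat_species_coupling")
  expect_error(landscape_config(spatial_range_km = 0), "spatial_range_km")
})

test_that("generated bundles honour the configured counts and structure", {
  cfg <- landscape_config(n_sites = 104, n_species = 131, seed = 7)
  b <- generate_landscape(cfg)
  expect_s3_class(b, "landscape_bundle")
  n_dual <- round(cfg$dual_designation_fraction * 104)
  expect_equal(nrow(b$sites), 104 + n_dual)
  expect_length(b$truth$species_pool, 131)
  # every composition row references an existing site id
  expect_true(all(b$compositions$site_id %in% b$sites$site_id))
  # dual-designation partnership is symmetric and at equal coordinates
  has_p <- nzchar(b$sites$zero_distance_partners)
  expect_equal(sum(has_p), 2 * n_dual)
  for (i in which(has_p)) {
    p <- b$sites$zero_distance_partners[i]
    j <- match(p, b$sites$site_id)
    expect_identical(b$sites$zero_distance_partners[j],
                     b$sites$site_id[i])
    expect_identical(b$sites$x_km[i], b$sites$x_km[j])
  }
  tmp <- withr::local_tempdir()
  paths <- write_landscape(b, tmp)
  expect_identical(read_site_table(paths[["sites"]])$site_id,
                   b$sites$site_id)
  expect_equal(nrow(read_composition_table(paths[["compositions"]])),
               nrow(b$compositions))
})

test_that("identical config and seed give byte-identical tables", {
  cfg <- landscape_config(n_sites = 40, seed = 11)
  b1 <- generate_landscape(cfg)
  b2 <- generate_landscape(cfg)
  expect_identical(b1$sites, b2$sites)
  expect_identical(b1$compositions, b2$compositions)
  b3 <- generate_landscape(landscape_config(n_sites = 40, seed = 12))
  expect_false(identical(b1$sites, b3$sites))
})

test_that("zero coupling decouples species sets from habitat similarity", {
  b <- generate_landscape(landscape_config(habitat_species_coupling = 0,
                                           seed = 1))
  sites <- filter_sites(b$sites, TRUE, TRUE)
  Sh <- pairwise_similarity(
    build_vector_set(b$compositions, sites, "habitat", "binary"),
    "jaccard")
  Ss <- pairwise_similarity(
    build_vector_set(b$compositions, sites, "species", "binary"),
    "jaccard")
  # non-partner pairs only: partner nodes duplicate compositions
  D <- compute_distances(sites, "planar")
  up <- upper.tri(Sh) & D > 0
  rho <- spearman(Sh[up], Ss[up])
  expect_lt(abs(rho), 0.15)
})

test_that("habitat-species coupling raises species overlap among similar sites", {
  top_decile_overlap <- function(coupling, seed) {
    b <- generate_landscape(landscape_config(
      habitat_species_coupling = coupling, n_sites = 60,
      dual_designation_fraction = 0, missing_data_fraction = 0,
      seed = seed))
    Sh <- pairwise_similarity(
      build_vector_set(b$compositions, b$sites, "habitat", "binary"),
      "jaccard")
    Ss <- pairwise_similarity(
      build_vector_set(b$compositions, b$sites, "species", "binary"),
      "jaccard")
    up <- upper.tri(Sh)
    cut <- stats::quantile(Sh[up], 0.9)
    mean(Ss[up][Sh[up] >= cut])
  }
  o <- sapply(c(0, 10, 60), function(cpl) {
    mean(vapply(1:3, function(s) top_decile_overlap(cpl, s), 0))
  })
  expect_true(all(diff(o) >= 0))
  expect_gt(o[3], o[1])
})

test_that("missing-data injection flags sites and removes their land use", {
  b <- generate_landscape(landscape_config(
    n_sites = 50, missing_data_fraction = 0, seed = 3))
  expect_identical(inject_missing_data(b, 0), b)
  all_flagged <- inject_missing_data(b, 1, seed = 1)
  expect_true(all(all_flagged$sites$missing_landuse))
  expect_false(any(all_flagged$compositions$dataset == "landuse"))
  # the case-study arithmetic: 107 usable minus 3 flagged leaves 104
  b107 <- generate_landscape(landscape_config(
    n_sites = 107, dual_designation_fraction = 0,
    missing_data_fraction = 0, seed = 5))
  b107 <- inject_missing_data(b107, 3 / 107, seed = 9)
  expect_equal(sum(b107$sites$missing_landuse), 3)
  kept <- filter_sites(b107$sites, require_landuse = TRUE,
                       mainland_only = TRUE)
  expect_equal(nrow(kept), 104)
})

test_that("zero-distance partners come out at distance zero downstream", {
  b <- generate_landscape(landscape_config(n_sites = 30, seed = 2))
  D <- compute_distances(b$sites, "planar")
  for (i in which(nzchar(b$sites$zero_distance_partners))) {
    expect_identical(
      D[b$sites$site_id[i], b$sites$zero_distance_partners[i]], 0)
  }
})
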