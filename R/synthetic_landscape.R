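# Synthetic landscape generator: seedable site/composition/occupancy
# data with the statistical structure the downstream analysis assumes —
# spatially autocorrelated habitat composition, species occupancy
# coupled to habitat affinity, land-use composition independent of
# species, and dual SPA/SCI designations at zero distance.

#' Configuration for the synthetic landscape generator
#'
#' Defaults emulate a regional protected-site network of the case-study
#' scale: roughly a hundred sites in a 135 km square (which puts about
#' an eighth of site pairs within the 30 km distance threshold, so the
#' raw-distance graph has several hundred edges), a pool of 131
#' species with a specialist-to-generalist gradient, and a few percent
#' of sites with missing land-use data.
#'
#' @param n_sites number of base sites (dual-designation duplicates are
#'   emitted on top of these).
#' @param region_extent_km side of the square study region, km.
#' @param n_species species pool size.
#' @param n_habitat_codes,n_landuse_codes attribute pool sizes.
#' @param dual_designation_fraction fraction of sites emitted as
#'   overlapping SPA+SCI node pairs at zero distance.
#' @param missing_data_fraction fraction of site records flagged as
#'   missing land-use composition.
#' @param habitat_species_coupling strength (>= 0) with which a site's
#'   habitat composition drives species occupancy; 0 makes occupancy
#'   independent of habitat.
#' @param spatial_range_km e-folding range of the spatial
#'   autocorrelation of habitat composition.
#' @param patches_per_site_mean mean number of composition patches per
#'   site and dataset.
#' @param prevalence_intercept intercept of the occupancy logit,
#'   controlling overall species prevalence.
#' @param n_archetypes number of regional habitat archetype mixtures.
#' @param site_mix_concentration Dirichlet concentration of each site's
#'   habitat mixture around the interpolated regional field; smaller
#'   values give sites more idiosyncratic composition.
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical tables.
#' @return A validated `landscape_config` list.
#' @export
landscape_config <- function(n_sites = 100,
                             region_extent_km = 135,
                             n_species = 131,
                             n_habitat_codes = 40,
                             n_landuse_codes = 30,
                             dual_designation_fraction = 0.10,
                             missing_data_fraction = 0.03,
                             habitat_species_coupling = 60,
                             spatial_range_km = 25,
                             patches_per_site_mean = 10,
                             prevalence_intercept = -1.5,
                             n_archetypes = 6,
                             site_mix_concentration = 45,
                             seed = 1) {
  cfg <- list(
    n_sites = check_count(n_sites, "n_sites"),
    region_extent_km = check_positive(region_extent_km,
                                      "region_extent_km"),
    n_species = check_count(n_species, "n_species"),
    n_habitat_codes = check_count(n_habitat_codes, "n_habitat_codes"),
    n_landuse_codes = check_count(n_landuse_codes, "n_landuse_codes"),
    dual_designation_fraction =
      check_fraction(dual_designation_fraction,
                     "dual_designation_fraction"),
    missing_data_fraction =
      check_fraction(missing_data_fraction, "missing_data_fraction"),
    habitat_species_coupling = habitat_species_coupling,
    spatial_range_km = check_positive(spatial_range_km,
                                      "spatial_range_km"),
    patches_per_site_mean = check_positive(patches_per_site_mean,
                                           "patches_per_site_mean"),
    prevalence_intercept = prevalence_intercept,
    n_archetypes = check_count(n_archetypes, "n_archetypes"),
    site_mix_concentration = check_positive(site_mix_concentration,
                                            "site_mix_concentration"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(habitat_species_coupling) ||
      length(habitat_species_coupling) != 1L ||
      is.na(habitat_species_coupling) || habitat_species_coupling < 0) {
    stop_field("habitat_species_coupling",
               "must be a single number >= 0")
  }
  if (!is.numeric(prevalence_intercept) ||
      length(prevalence_intercept) != 1L || is.na(prevalence_intercept)) {
    stop_field("prevalence_intercept", "must be a single number")
  }
  structure(cfg, class = "landscape_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1)] <- 1
  g / sum(g)
}

cosine_rows <- function(M, v) {
  # cosine between each row of M and vector v (all non-negative)
  num <- as.numeric(M %*% v)
  den <- sqrt(rowSums(M^2)) * sqrt(sum(v^2))
  ifelse(den == 0, 0, num / den)
}

# Composition rows for one site from a mixture over codes. A code is
# reported present when it holds at least `min_share` of the site's
# mixture (inventories record types exceeding a minimal areal share,
# not a random sample of patches), so presence is a deterministic
# function of the mixture; patch counts beyond one-per-type are drawn
# multinomially and areas follow the mixture with noise.
draw_patches <- function(site_id, dataset, codes, mixture, mean_patches,
                         total_area_ha, min_share = 0.025) {
  present <- which(mixture >= min_share | mixture == max(mixture))
  k <- length(present)
  n_patches <- 1L + stats::rpois(1, max(mean_patches - 1, 0))
  counts <- rep(1L, k)
  if (n_patches > k) {
    counts <- counts + as.integer(
      stats::rmultinom(1, n_patches - k, mixture[present]))
  }
  w <- mixture[present] * stats::rgamma(k, shape = 4, rate = 4)
  area <- round(total_area_ha * w / sum(w), 2)
  data.frame(site_id = site_id, dataset = dataset,
             code = codes[present], count = counts,
             area_ha = area, stringsAsFactors = FALSE)
}

#' Generate a synthetic landscape
#'
#' Produces a site table and composition table with the structure the
#' analysis assumes:
#' \itemize{
#'   \item site coordinates uniform in the square region (planar km);
#'   \item a fraction of sites duplicated as SPA/SCI node pairs at
#'     identical coordinates, registered as mutual zero-distance
#'     partners;
#'   \item habitat composition interpolated from a small set of regional
#'     archetype mixtures with exponentially distance-decaying weights
#'     (range `spatial_range_km`), so nearby sites have similar habitat
#'     mixes;
#'   \item land-use composition drawn around a common regional land-use
#'     mixture, independently of species occupancy;
#'   \item species occupancy drawn per (site, species) with probability
#'     `plogis(intercept + coupling * z)`, where `z` is the cosine
#'     affinity between the site's habitat mixture and the species'
#'     preferred-habitat profile, standardized per species — so the
#'     coupling is in log-odds per SD of habitat affinity, monotone in
#'     the affinity, and coupling 0 makes occupancy independent of
#'     habitat;
#'   \item a fraction of site records flagged as missing land-use data
#'     (rows removed), feeding the pipeline's site filter.
#' }
#'
#' @param config a [landscape_config].
#' @return A `landscape_bundle`: list with `sites` (site `data.frame`,
#'   planar coordinates), `compositions` (composition `data.frame`) and
#'   `truth` (generation internals for recovery tests: config, habitat
#'   mixtures, species preference matrix, occupancy matrix, affinities).
#' @export
generate_landscape <- function(config) {
  if (!inherits(config, "landscape_config")) {
    config <- do.call(landscape_config, as.list(config))
  }
  cfg <- config
  with_seed(cfg$seed, {
    L <- cfg$region_extent_km
    n <- cfg$n_sites
    base_id <- sprintf("S%03d", seq_len(n))
    x <- stats::runif(n, 0, L)
    y <- stats::runif(n, 0, L)

    hab_codes <- sort(sprintf("%04d", sample(1000:9999, cfg$n_habitat_codes)))
    # CLC level-3 style codes: major class 1-5, two sub-digits
    lu_pool <- with(expand.grid(a = 1:5, b = 1:4, c = 1:9),
                    sprintf("%d%d%d", a, b, c))
    if (cfg$n_landuse_codes > length(lu_pool)) {
      stop_field("n_landuse_codes",
                 sprintf("at most %d CLC-style codes available",
                         length(lu_pool)))
    }
    lu_codes <- sort(sample(lu_pool, cfg$n_landuse_codes))
    sp_codes <- sort(sprintf("%04d", sample(1000:9999, cfg$n_species)))

    # regional habitat archetypes + distance-decaying interpolation;
    # archetypes are distinct sparse mixtures, so habitat composition
    # carries a real spatial signal for species occupancy to track
    # spatially stratified placement (one archetype per grid cell,
    # jittered): regional communities tile the region rather than
    # clumping by chance
    nc <- ceiling(sqrt(cfg$n_archetypes))
    nr <- ceiling(cfg$n_archetypes / nc)
    cells <- utils::head(expand.grid(cx = seq_len(nc), cy = seq_len(nr)),
                         cfg$n_archetypes)
    arch_xy <- cbind((cells$cx - stats::runif(cfg$n_archetypes)) * L / nc,
                     (cells$cy - stats::runif(cfg$n_archetypes)) * L / nr)
    arch_mix <- t(vapply(seq_len(cfg$n_archetypes),
                         function(k) rdirichlet1(rep(0.3, length(hab_codes))),
                         numeric(length(hab_codes))))
    dist_arch <- sqrt(outer(x, arch_xy[, 1], `-`)^2 +
                        outer(y, arch_xy[, 2], `-`)^2)
    W <- exp(-dist_arch / cfg$spatial_range_km)
    W <- W / rowSums(W)
    blended <- W %*% arch_mix
    # site-level heterogeneity on top of the regional field: each site
    # redraws its mixture around the blended one; the concentration
    # sets how faithfully sites track their surroundings
    hab_mix <- t(vapply(seq_len(n), function(i) {
      rdirichlet1(blended[i, ] * cfg$site_mix_concentration)
    }, numeric(length(hab_codes))))
    rownames(hab_mix) <- base_id
    colnames(hab_mix) <- hab_codes

    # common regional land-use base: widespread classes dominate
    lu_base <- rdirichlet1(rep(0.5, length(lu_codes)))
    lu_mix <- t(vapply(seq_len(n),
                       function(i) rdirichlet1(lu_base * 8),
                       numeric(length(lu_codes))))
    colnames(lu_mix) <- lu_codes

    # habitat and land-use composition rows per base site; the
    # reported habitat area shares are what species respond to below
    total_area <- round(stats::rlnorm(n, log(1500), 0.6), 2)
    hab_rows <- lapply(seq_len(n), function(i) {
      draw_patches(base_id[i], "habitat", hab_codes, hab_mix[i, ],
                   cfg$patches_per_site_mean, total_area[i])
    })
    lu_rows <- lapply(seq_len(n), function(i) {
      draw_patches(base_id[i], "landuse", lu_codes, lu_mix[i, ],
                   cfg$patches_per_site_mean, total_area[i])
    })
    hab_share <- matrix(0, n, length(hab_codes),
                        dimnames = list(base_id, hab_codes))
    for (i in seq_len(n)) {
      r <- hab_rows[[i]]
      hab_share[i, r$code] <- r$area_ha / sum(r$area_ha)
    }

    # species preferences over habitat codes: each species belongs to a
    # habitat community and prefers a profile close to one regional
    # archetype mixture, as species track vegetation communities
    sp_home <- sample.int(cfg$n_archetypes, cfg$n_species, replace = TRUE)
    sp_pref <- t(vapply(seq_len(cfg$n_species), function(s) {
      rdirichlet1(arch_mix[sp_home[s], ] * 50)
    }, numeric(length(hab_codes))))
    rownames(sp_pref) <- sp_codes
    # affinity is the cosine (Ochiai) overlap between the site's
    # reported habitat presence profile and the species' preferred
    # habitat set (profile thresholded at the same minimal share used
    # for reporting): what counts is which of its preferred habitat
    # types a site hosts
    hab_presence <- (hab_share > 0) * 1
    affinity <- vapply(seq_len(cfg$n_species),
                       function(s) cosine_rows(hab_presence, sp_pref[s, ]),
                       numeric(n))  # sites x species
    dimnames(affinity) <- list(base_id, sp_codes)
    # standardize affinity per species so the coupling is in log-odds
    # per SD of habitat affinity; a sharp logistic (high coupling)
    # makes occupancy nearly deterministic given habitat, which is what
    # lets similar sites host near-identical species sets
    aff_z <- apply(affinity, 2, function(a) {
      s <- stats::sd(a)
      if (s == 0) rep(0, length(a)) else (a - mean(a)) / s
    })
    # per-species heterogeneity, as in real assemblages: coupling
    # multipliers separate habitat specialists from quasi-random
    # generalists, and a range-size (prevalence) distribution on the
    # logit scale; the intercept is solved per species (logit-normal
    # mean approximation) so prevalence stays near its target at any
    # coupling
    c_s <- cfg$habitat_species_coupling *
      stats::rgamma(cfg$n_species, shape = 1, rate = 1)
    l_s <- cfg$prevalence_intercept + stats::rnorm(cfg$n_species)
    a_s <- l_s * sqrt(1 + (0.588 * c_s)^2)
    p_occ <- stats::plogis(
      matrix(a_s, n, cfg$n_species, byrow = TRUE) +
        sweep(aff_z, 2, c_s, `*`))
    dimnames(p_occ) <- dimnames(affinity)
    occupancy <- matrix(stats::rbinom(length(p_occ), 1, p_occ),
                        nrow = n, dimnames = dimnames(p_occ))

    sp_rows <- lapply(seq_len(n), function(i) {
      occ <- sp_codes[occupancy[i, ] == 1]
      if (length(occ) == 0) return(NULL)
      data.frame(site_id = base_id[i], dataset = "species", code = occ,
                 count = 1L, area_ha = 0, stringsAsFactors = FALSE)
    })
    compositions <- do.call(rbind, Filter(Negate(is.null),
                                          c(hab_rows, lu_rows, sp_rows)))

    # designations; dual sites become SPA/SCI partner node pairs
    n_dual <- round(cfg$dual_designation_fraction * n)
    dual_idx <- sort(sample.int(n, n_dual))
    desig <- sample(c("SPA", "SCI"), n, replace = TRUE)
    sites <- data.frame(site_id = base_id, designations = desig,
                        x_km = round(x, 3), y_km = round(y, 3),
                        zero_distance_partners = "",
                        missing_landuse = FALSE, on_mainland = TRUE,
                        stringsAsFactors = FALSE)
    if (n_dual > 0) {
      partner_id <- paste0(base_id[dual_idx], "P")
      sites$designations[dual_idx] <- "SPA"
      sites$zero_distance_partners[dual_idx] <- partner_id
      partners <- data.frame(site_id = partner_id, designations = "SCI",
                             x_km = sites$x_km[dual_idx],
                             y_km = sites$y_km[dual_idx],
                             zero_distance_partners = base_id[dual_idx],
                             missing_landuse = FALSE, on_mainland = TRUE,
                             stringsAsFactors = FALSE)
      sites <- rbind(sites, partners)
      # the partner node reports the same compositions
      dup <- compositions[compositions$site_id %in% base_id[dual_idx], ,
                          drop = FALSE]
      dup$site_id <- paste0(dup$site_id, "P")
      compositions <- rbind(compositions, dup)
    }
    sites <- sites[order(sites$site_id), , drop = FALSE]
    rownames(sites) <- NULL
    compositions <- compositions[order(compositions$site_id,
                                       compositions$dataset,
                                       compositions$code), , drop = FALSE]
    rownames(compositions) <- NULL
    attr(sites, "coord_mode") <- "planar"

    bundle <- structure(
      list(sites = sites, compositions = compositions,
           truth = list(config = cfg, habitat_mixtures = hab_mix,
                        landuse_mixtures = lu_mix,
                        species_preferences = sp_pref,
                        affinity = affinity, occupancy = occupancy,
                        species_pool = sp_codes,
                        habitat_pool = hab_codes,
                        landuse_pool = lu_codes)),
      class = "landscape_bundle")
    if (cfg$missing_data_fraction > 0) {
      bundle <- inject_missing_data(bundle, cfg$missing_data_fraction,
                                    seed = cfg$seed)
    }
    bundle
  })
}

#' Flag a random fraction of sites as missing land-use data
#'
#' Marks the chosen site records with `missing_landuse = TRUE` and
#' removes their land-use composition rows, emulating incomplete
#' regional land-cover coverage; flagged sites are then excluded by
#' [filter_sites] with `require_landuse = TRUE`.
#'
#' @param bundle a `landscape_bundle`.
#' @param fraction fraction of site records to flag, in `[0, 1]`.
#' @param seed RNG seed for the site draw.
#' @return The modified bundle.
#' @export
inject_missing_data <- function(bundle, fraction, seed = 0L) {
  check_fraction(fraction, "fraction")
  if (fraction == 0) return(bundle)
  n <- nrow(bundle$sites)
  k <- round(fraction * n)
  if (k == 0) return(bundle)
  with_seed(seed, {
    idx <- sort(sample.int(n, k))
    flagged <- bundle$sites$site_id[idx]
    bundle$sites$missing_landuse[idx] <- TRUE
    drop <- bundle$compositions$dataset == "landuse" &
      bundle$compositions$site_id %in% flagged
    bundle$compositions <- bundle$compositions[!drop, , drop = FALSE]
    rownames(bundle$compositions) <- NULL
    bundle
  })
}

#' @export
print.landscape_bundle <- function(x, ...) {
  cat(sprintf(paste0("<landscape_bundle | %d site records, %d composition",
                     " rows, %d species in pool>\n"),
              nrow(x$sites), nrow(x$compositions),
              length(x$truth$species_pool)))
  invisible(x)
}

#' Species occupancy sets from a composition table
#' @param compositions composition `data.frame`.
#' @return Named list (species code -> character vector of occupied
#'   site ids).
#' @export
species_occupancy <- function(compositions) {
  sp <- compositions[compositions$dataset == "species", , drop = FALSE]
  split(sp$site_id, sp$code)
}

#' Write a landscape bundle to disk
#'
#' Emits the two CSV tables consumed by the pipeline readers plus a
#' JSON sidecar recording the generating configuration and summary
#' statistics (not the full truth matrices).
#'
#' @param bundle a `landscape_bundle`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_landscape <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sites = file.path(dir, "sites.csv"),
             compositions = file.path(dir, "compositions.csv"),
             truth = file.path(dir, "truth.json"))
  write_site_table(bundle$sites, paths[["sites"]])
  write_composition_table(bundle$compositions, paths[["compositions"]])
  truth <- c(bundle$truth$config,
             list(n_site_records = nrow(bundle$sites),
                  n_composition_rows = nrow(bundle$compositions),
                  mean_occupancy = mean(bundle$truth$occupancy)))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
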