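# End-to-end orchestration: generate or load tables, build vectors,
# similarities and the four graph families, compute indices, evaluate
# hit rates and correlations, and report candidate sites.

#' Default similarity-graph recipes
#'
#' The seven (dataset, mode, measure) combinations the analysis
#' compares: Jaccard on binary species, habitat and land-use vectors,
#' and cosine on occurrence-count and area-weighted habitat and
#' land-use vectors. Species vectors are binary only, so no species
#' cosine recipes exist.
#'
#' @return A named list of recipes, each a list with `dataset`, `mode`,
#'   `measure`.
#' @export
default_recipes <- function() {
  list(
    landuse_jaccard = list(dataset = "landuse", mode = "binary",
                           measure = "jaccard"),
    habitat_jaccard = list(dataset = "habitat", mode = "binary",
                           measure = "jaccard"),
    species_jaccard = list(dataset = "species", mode = "binary",
                           measure = "jaccard"),
    landuse_count_cosine = list(dataset = "landuse", mode = "count",
                                measure = "cosine"),
    habitat_count_cosine = list(dataset = "habitat", mode = "count",
                                measure = "cosine"),
    landuse_area_cosine = list(dataset = "landuse", mode = "area",
                               measure = "cosine"),
    habitat_area_cosine = list(dataset = "habitat", mode = "area",
                               measure = "cosine")
  )
}

validate_recipes <- function(recipes) {
  if (is.null(names(recipes)) || any(!nzchar(names(recipes)))) {
    stop("recipes must be a named list")
  }
  for (lab in names(recipes)) {
    r <- recipes[[lab]]
    if (!all(c("dataset", "mode", "measure") %in% names(r))) {
      stop("recipe '", lab, "' must have dataset, mode and measure")
    }
    if (!r$dataset %in% c("species", "habitat", "landuse") ||
        !r$mode %in% c("binary", "count", "area") ||
        !r$measure %in% c("jaccard", "cosine")) {
      stop("recipe '", lab, "' has an unknown dataset/mode/measure token")
    }
    if (r$dataset == "species" &&
        (r$mode != "binary" || r$measure != "jaccard")) {
      stop("recipe '", lab, "': species vectors are binary ",
           "Jaccard only")
    }
    if (r$measure == "jaccard" && r$mode != "binary") {
      stop("recipe '", lab, "': jaccard requires binary mode")
    }
  }
  invisible(recipes)
}

#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs. Input is either a pair
#' of CSV paths (`sites_path`, `compositions_path`) or a synthetic
#' landscape configuration (the default).
#'
#' @param synthetic a [landscape_config], or `NULL` when reading files.
#' @param sites_path,compositions_path CSV inputs (used when
#'   `synthetic` is `NULL`).
#' @param distance_threshold_km geographical threshold, km (default 30).
#' @param similarity_threshold minimum similarity score (default 0.5).
#' @param sweep_levels similarity levels for the edge-count sweep.
#' @param recipes named list of similarity-graph recipes
#'   (default [default_recipes]).
#' @param candidate_recipe label of the recipe whose similarity graph
#'   backs the candidate finder.
#' @param require_landuse,mainland_only site filter flags.
#' @param seed integer seed for synthetic generation.
#' @return A validated `run_config` list.
#' @export
run_config <- function(synthetic = landscape_config(),
                       sites_path = NULL, compositions_path = NULL,
                       distance_threshold_km = 30,
                       similarity_threshold = 0.5,
                       sweep_levels = seq(0, 0.9, by = 0.1),
                       recipes = default_recipes(),
                       candidate_recipe = "habitat_jaccard",
                       require_landuse = TRUE, mainland_only = TRUE,
                       seed = NULL) {
  if (distance_threshold_km < 0) {
    stop_field("distance_threshold_km", "must be >= 0")
  }
  check_fraction(similarity_threshold, "similarity_threshold")
  if (any(sweep_levels < 0 | sweep_levels > 1)) {
    stop_field("sweep_levels", "must lie in [0, 1]")
  }
  validate_recipes(recipes)
  if (!candidate_recipe %in% names(recipes)) {
    stop_field("candidate_recipe", "not among the recipe labels")
  }
  if (!is.null(synthetic)) {
    if (!inherits(synthetic, "landscape_config")) {
      synthetic <- do.call(landscape_config, as.list(synthetic))
    }
    if (!is.null(seed)) synthetic$seed <- check_count(seed, "seed", 0L)
  } else if (is.null(sites_path) || is.null(compositions_path)) {
    stop("supply either a synthetic config or both input paths")
  }
  structure(list(synthetic = synthetic, sites_path = sites_path,
                 compositions_path = compositions_path,
                 distance_threshold_km = distance_threshold_km,
                 similarity_threshold = similarity_threshold,
                 sweep_levels = sweep_levels, recipes = recipes,
                 candidate_recipe = candidate_recipe,
                 require_landuse = require_landuse,
                 mainland_only = mainland_only),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the site and composition tables, filters sites,
#' computes distances and the raw-distance graph, then per recipe the
#' vector set, similarity matrix, similarity graph at the configured
#' threshold, edge-count sweep and node-index table; builds the full
#' single-species graph battery for every species in the composition
#' table; and evaluates hit rates, normalized hit rates, hit-rate and
#' index correlations and candidate sites. With `out_dir` set, all
#' tables and graphs are written along with a manifest (config, file
#' checksums, row counts); identical config and seed give identical
#' outputs.
#'
#' @param config a [run_config].
#' @param out_dir optional output directory.
#' @return A list of all intermediate and final objects, invisibly when
#'   `out_dir` is set: `sites`, `compositions`, `distances`,
#'   `raw_graph`, `vector_sets`, `similarities`, `sim_graphs`, `sweeps`,
#'   `index_tables`, `rate_table`, `evaluation`, `hit_rate_correlations`,
#'   `index_correlations`, `candidates`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$synthetic)) {
    bundle <- generate_landscape(config$synthetic)
    sites <- bundle$sites
    compositions <- bundle$compositions
  } else {
    sites <- read_site_table(config$sites_path)
    compositions <- read_composition_table(config$compositions_path)
  }
  sites <- filter_sites(sites, require_landuse = config$require_landuse,
                        mainland_only = config$mainland_only)
  compositions <- compositions[compositions$site_id %in% sites$site_id, ,
                               drop = FALSE]
  mode <- if (identical(attr(sites, "coord_mode"), "lonlat"))
    "geodesic" else "planar"
  D <- compute_distances(sites, mode = mode)
  thr <- config$distance_threshold_km
  raw <- build_raw_distance(sites, D, thr)

  vector_sets <- list(); similarities <- list()
  sim_graphs <- list(); sweeps <- list(); index_tables <- list()
  for (lab in names(config$recipes)) {
    r <- config$recipes[[lab]]
    vs <- build_vector_set(compositions, sites, r$dataset, r$mode)
    S <- pairwise_similarity(vs, r$measure)
    g <- build_similarity_graph(sites, D, S, thr,
                                config$similarity_threshold)
    vector_sets[[lab]] <- vs
    similarities[[lab]] <- S
    sim_graphs[[lab]] <- g
    sweeps[[lab]] <- edge_count_sweep(sites, D, S, thr,
                                      config$sweep_levels)
    index_tables[[lab]] <- compute_indices(g)
  }

  occ <- species_occupancy(compositions)
  species_graphs <- lapply(names(occ), function(code) {
    build_single_species(occ[[code]], sites, D, thr, full = TRUE,
                         species_code = code)
  })
  names(species_graphs) <- names(occ)

  rate_table <- hit_rate_table(species_graphs, sim_graphs)
  evaluation <- evaluate_graphs(rate_table, sim_graphs, n_edges(raw))

  labs <- names(sim_graphs)
  pairing <- utils::combn(labs, 2, simplify = FALSE)
  hr_corr <- correlate_hit_rates(rate_table, pairing)
  idx_corr <- do.call(rbind, lapply(
    c("degree", "betweenness", "closeness", "clustering", "topological"),
    function(ix) correlate_indices(index_tables, ix, pairing)))

  cand_graph <- sim_graphs[[config$candidate_recipe]]
  candidates <- lapply(names(occ), function(code) {
    sp <- build_single_species(occ[[code]], sites, D, thr, full = FALSE,
                               species_code = code)
    candidate_table(find_candidates(sp, cand_graph))
  })
  names(candidates) <- names(occ)
  candidates_all <- do.call(rbind, candidates)
  rownames(candidates_all) <- NULL

  out <- list(config = config, sites = sites,
              compositions = compositions, distances = D,
              raw_graph = raw, vector_sets = vector_sets,
              similarities = similarities, sim_graphs = sim_graphs,
              sweeps = sweeps, index_tables = index_tables,
              species_graphs = species_graphs, rate_table = rate_table,
              evaluation = evaluation,
              hit_rate_correlations = hr_corr,
              index_correlations = idx_corr,
              candidates = candidates_all)
  if (is.null(out_dir)) return(out)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(obj, name, writer = utils::write.csv, ...) {
    p <- file.path(out_dir, name)
    writer(obj, p, ...)
    files <<- c(files, p)
    p
  }
  wr(sites, "sites.csv", row.names = FALSE)
  wr(compositions, "compositions.csv", row.names = FALSE)
  wr(rate_table, "hit_rates.csv", row.names = FALSE)
  wr(evaluation, "evaluation.csv", row.names = FALSE)
  wr(hr_corr, "hit_rate_correlations.csv", row.names = FALSE)
  wr(idx_corr, "index_correlations.csv", row.names = FALSE)
  wr(candidates_all, "candidates.csv", row.names = FALSE)
  for (lab in labs) {
    wr(sweeps[[lab]], paste0("sweep_", lab, ".csv"), row.names = FALSE)
    wr(index_tables[[lab]], paste0("indices_", lab, ".csv"),
       row.names = FALSE)
    p <- file.path(out_dir, paste0("graph_", lab, ".graphml"))
    write_eco_graph(sim_graphs[[lab]], p, "graphml",
                    node_attrs = sites[, c("site_id", "designations")])
    files <- c(files, p)
  }
  p <- file.path(out_dir, "graph_raw_distance.graphml")
  write_eco_graph(raw, p, "graphml",
                  node_attrs = sites[, c("site_id", "designations")])
  files <- c(files, p)

  manifest <- list(
    package_version = as.character(utils::packageVersion("econetsim")),
    distance_threshold_km = thr,
    similarity_threshold = config$similarity_threshold,
    seed = if (!is.null(config$synthetic)) config$synthetic$seed else NULL,
    n_sites = nrow(sites), n_species = length(occ),
    n_raw_edges = n_edges(raw),
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(md5 = unname(tools::md5sum(f)),
           bytes = unname(file.size(f)))
    })
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}

#' Render a run as an aligned text report
#'
#' Sections cover, in order: the per-recipe edge-count
#' sweeps, the evaluation summary (average hit rate, edges, relative
#' density, normalized hit rate), the hit-rate and index correlation
#' matrices, and a per-species candidate summary (`no candidates` when
#' a species has none).
#'
#' @param run output of [run_pipeline].
#' @return Character vector of report lines, invisibly; printed when
#'   `print = TRUE`.
#' @param print print the report to the console?
#' @export
make_report <- function(run, print = TRUE) {
  fmt_tab <- function(df) {
    utils::capture.output(print(format(df, digits = 5),
                                row.names = FALSE))
  }
  lines <- c("== Similarity-graph edge-count sweeps ==")
  for (lab in names(run$sweeps)) {
    lines <- c(lines, paste0("-- ", lab, " --"),
               fmt_tab(run$sweeps[[lab]]), "")
  }
  lines <- c(lines, "== Evaluation summary (hit rates) ==",
             fmt_tab(run$evaluation), "",
             "== Spearman correlation of hit rates ==",
             fmt_tab(run$hit_rate_correlations), "",
             "== Spearman correlation of node indices ==",
             fmt_tab(run$index_correlations), "",
             "== Candidate sites ==")
  n_cand <- table(factor(run$candidates$species_code,
                         levels = names(run$species_graphs)))
  for (code in names(n_cand)) {
    lines <- c(lines,
               if (n_cand[[code]] == 0) {
                 paste0(code, ": no candidates")
               } else {
                 sprintf("%s: %d candidate edge(s)", code, n_cand[[code]])
               })
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
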