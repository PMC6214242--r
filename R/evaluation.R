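# Evaluation of similarity-based graphs against single-species graphs:
# edge hit rates, normalized hit rates, Spearman correlation tables and
# the candidate-site finder.

#' Edge hit rate of a similarity graph against a species graph
#'
#' Counts how many of the single-species graph's edges (`m`) are present
#' in the similarity-based graph (`h`, the hits) and returns the rate
#' `h / m`. Both graphs must share the geographical distance threshold,
#' otherwise the comparison is meaningless. A species with no edges has
#' an undefined rate (`NA`).
#'
#' @param species_graph an [eco_graph] (single-species, full or not; the
#'   edge set is identical).
#' @param sim_graph an [eco_graph] of kind `"similarity"` (any graph
#'   works; edges are compared as sets).
#' @return A list with elements `m`, `h`, `rate`.
#' @export
hit_rate <- function(species_graph, sim_graph) {
  t1 <- species_graph$params$distance_threshold_km
  t2 <- sim_graph$params$distance_threshold_km
  if (!is.null(t1) && !is.null(t2) && !isTRUE(all.equal(t1, t2))) {
    stop("graphs built with different distance thresholds: ",
         t1, " vs ", t2)
  }
  m <- n_edges(species_graph)
  h <- length(intersect(edge_keys(species_graph), edge_keys(sim_graph)))
  list(m = m, h = h, rate = if (m > 0) h / m else NA_real_)
}

#' Hit-rate table over a battery of species and similarity graphs
#'
#' One row per species, one `hits_<label>` / `rate_<label>` column pair
#' per similarity graph — the layout of the per-species
#' hit-rate table.
#'
#' @param species_graphs named list of single-species [eco_graph]s
#'   (names = species codes).
#' @param sim_graphs named list of similarity [eco_graph]s
#'   (names = graph labels).
#' @return A `data.frame` with columns `species_code`, `m`, then hits
#'   and rates per graph label.
#' @export
hit_rate_table <- function(species_graphs, sim_graphs) {
  stopifnot(length(species_graphs) > 0, length(sim_graphs) > 0)
  out <- data.frame(species_code = names(species_graphs),
                    m = vapply(species_graphs, n_edges, integer(1)),
                    stringsAsFactors = FALSE)
  sim_keys <- lapply(sim_graphs, edge_keys)
  sp_keys <- lapply(species_graphs, edge_keys)
  for (lab in names(sim_graphs)) {
    h <- vapply(sp_keys, function(k) {
      length(intersect(k, sim_keys[[lab]]))
    }, integer(1))
    out[[paste0("hits_", lab)]] <- h
    out[[paste0("rate_", lab)]] <- ifelse(out$m > 0, h / out$m, NA_real_)
  }
  rownames(out) <- NULL
  out
}

#' Summarize a similarity graph's hit rates (normalized hit rate)
#'
#' Computes the average hit rate `R` (unweighted mean over species with
#' at least one single-species edge; species with `m = 0` have an
#' undefined rate and are excluded by default), the relative density
#' `|E| / n` of the similarity graph against the raw-distance graph, and
#' the normalized hit rate `R * n / |E|` — the average hit rate divided
#' by the relative density, which corrects for the higher expected hit
#' rate of denser graphs.
#'
#' @param rates numeric vector of per-species hit rates (NA = undefined),
#'   or `NULL` when `R` is supplied directly.
#' @param E similarity-graph edge count (> 0).
#' @param n raw-distance-graph edge count (> 0).
#' @param label graph label carried into the output.
#' @param R optional pre-computed average hit rate, bypassing `rates`.
#' @param include_undefined treat undefined rates as 0 instead of
#'   excluding them (default `FALSE`).
#' @return A one-row `data.frame` with columns `label`, `R`, `E`, `n`,
#'   `density`, `nhr`.
#' @export
summarize_hit_rates <- function(rates = NULL, E, n, label = "",
                                R = NULL, include_undefined = FALSE) {
  if (n <= 0) stop("raw-distance edge count n must be positive")
  if (E <= 0) stop("normalized hit rate undefined for E = 0")
  if (is.null(R)) {
    if (is.null(rates)) stop("supply either rates or R")
    if (include_undefined) rates[is.na(rates)] <- 0
    R <- mean(rates, na.rm = TRUE)
  }
  density <- E / n
  data.frame(label = label, R = R, E = as.integer(E), n = as.integer(n),
             density = density, nhr = R / density,
             stringsAsFactors = FALSE)
}

#' Evaluation summary for a battery of similarity graphs
#'
#' Applies [summarize_hit_rates] to every similarity graph of a
#' [hit_rate_table], using the raw-distance edge count as `n`.
#'
#' @param rate_table output of [hit_rate_table].
#' @param sim_graphs the named list of similarity graphs used.
#' @param n raw-distance-graph edge count.
#' @param include_undefined see [summarize_hit_rates].
#' @return A `data.frame` with one row per graph label.
#' @export
evaluate_graphs <- function(rate_table, sim_graphs, n,
                            include_undefined = FALSE) {
  rows <- lapply(names(sim_graphs), function(lab) {
    summarize_hit_rates(rate_table[[paste0("rate_", lab)]],
                        E = n_edges(sim_graphs[[lab]]), n = n,
                        label = lab,
                        include_undefined = include_undefined)
  })
  do.call(rbind, rows)
}

#' Spearman rank correlation with listwise deletion
#'
#' Pearson correlation of mid-ranks (average ranks for ties). Pairs with
#' an undefined entry in either vector are dropped listwise before
#' ranking; fewer than 3 complete pairs, or zero rank variance in either
#' vector, is an error.
#'
#' @param a,b numeric vectors of equal length (NA = undefined).
#' @return Spearman's rho.
#' @export
spearman <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("fewer than 3 complete pairs")
  a <- a[ok]; b <- b[ok]
  if (stats::var(rank(a)) == 0 || stats::var(rank(b)) == 0) {
    stop("zero rank variance: correlation undefined")
  }
  stats::cor(a, b, method = "spearman")
}

# table-level wrapper: a degenerate column (all-tied ranks, too few
# complete pairs) yields NA with a warning rather than aborting a run
spearman_or_na <- function(a, b) {
  tryCatch(spearman(a, b), error = function(e) {
    warning(conditionMessage(e), ": recording NA", call. = FALSE)
    NA_real_
  })
}

#' Spearman correlation between hit-rate columns
#'
#' @param rate_table output of [hit_rate_table].
#' @param pairing list of 2-element character vectors of graph labels.
#' @return A `data.frame` with columns `graph_a`, `graph_b`, `rho`,
#'   `n_species` (complete pairs used).
#' @export
correlate_hit_rates <- function(rate_table, pairing) {
  rows <- lapply(pairing, function(p) {
    a <- rate_table[[paste0("rate_", p[1])]]
    b <- rate_table[[paste0("rate_", p[2])]]
    if (is.null(a) || is.null(b)) {
      stop("unknown graph label in pairing: ", paste(p, collapse = "/"))
    }
    data.frame(graph_a = p[1], graph_b = p[2],
               rho = spearman_or_na(a, b),
               n_species = sum(!is.na(a) & !is.na(b)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation of a node index between graphs
#'
#' Correlates the values of one node index across pairs of graphs,
#' aligning nodes by id — the cross-graph index comparison of the
#' analysis. All graphs must share the node universe.
#'
#' @param index_tables named list of [compute_indices] tables.
#' @param index_name one of `"degree"`, `"betweenness"`, `"closeness"`,
#'   `"clustering"`, `"topological"`.
#' @param pairing list of 2-element character vectors of graph labels.
#' @return A `data.frame` with columns `index`, `graph_a`, `graph_b`,
#'   `rho`.
#' @export
correlate_indices <- function(index_tables, index_name, pairing) {
  rows <- lapply(pairing, function(p) {
    ta <- index_tables[[p[1]]]
    tb <- index_tables[[p[2]]]
    if (is.null(ta) || is.null(tb)) {
      stop("unknown graph label in pairing: ", paste(p, collapse = "/"))
    }
    if (!setequal(ta$node, tb$node)) {
      stop("graphs do not share a node universe: ",
           paste(p, collapse = "/"))
    }
    b <- tb[[index_name]][match(ta$node, tb$node)]
    data.frame(index = index_name, graph_a = p[1], graph_b = p[2],
               rho = spearman_or_na(ta[[index_name]], b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Find candidate relocation sites for a species
#'
#' For each connected component `V'` of the (non-full) single-species
#' graph, returns the pairs `(i, j)` with `i` in `V'`, `j` a site not
#' occupied by the species, and `(i, j)` an edge of the similarity-based
#' graph: `j` is then a candidate site for relocating part of the
#' species' population, and `(i, j)` the candidate edge connecting it to
#' the component. Isolated occupied sites form singleton components and
#' yield candidates too.
#'
#' @param species_graph single-species [eco_graph] (non-full: nodes are
#'   the occupied sites).
#' @param sim_graph similarity-based [eco_graph] on the full node set,
#'   built with the same distance threshold.
#' @return A list of candidate sets, one per component: each a list with
#'   `species_code`, `component` (occupied site ids) and `candidates`
#'   (`data.frame` with columns `i`, `j`).
#' @export
find_candidates <- function(species_graph, sim_graph) {
  t1 <- species_graph$params$distance_threshold_km
  t2 <- sim_graph$params$distance_threshold_km
  if (!is.null(t1) && !is.null(t2) && !isTRUE(all.equal(t1, t2))) {
    stop("graphs built with different distance thresholds")
  }
  occupied <- species_graph$nodes
  code <- species_graph$params$species_code
  ig <- as_igraph(species_graph)
  comp <- igraph::components(ig)
  membership <- comp$membership
  # adjacency in the similarity graph, indexed by node id
  adj <- split(c(sim_graph$edges$to, sim_graph$edges$from),
               c(sim_graph$edges$from, sim_graph$edges$to))
  lapply(seq_len(comp$no), function(k) {
    Vp <- occupied[membership == k]
    cand_i <- character(0); cand_j <- character(0)
    for (i in Vp) {
      nb <- adj[[i]]
      js <- nb[!(nb %in% occupied)]
      cand_i <- c(cand_i, rep(i, length(js)))
      cand_j <- c(cand_j, js)
    }
    ord <- order(cand_i, cand_j)
    list(species_code = code, component = sort(Vp),
         candidates = data.frame(i = cand_i[ord], j = cand_j[ord],
                                 stringsAsFactors = FALSE))
  })
}

#' Flatten candidate sets into one table
#' @param candidate_sets output of [find_candidates].
#' @return A `data.frame` with columns `species_code`, `component_id`,
#'   `i`, `j` (zero rows when there are no candidates).
#' @export
candidate_table <- function(candidate_sets) {
  rows <- lapply(seq_along(candidate_sets), function(k) {
    cs <- candidate_sets[[k]]
    if (nrow(cs$candidates) == 0) return(NULL)
    data.frame(species_code = cs$species_code %||% NA_character_,
               component_id = k, cs$candidates,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(species_code = character(0),
                      component_id = integer(0), i = character(0),
                      j = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
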