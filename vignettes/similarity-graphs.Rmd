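---
title: "Similarity-based graph models of site networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-based graph models of site networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(econetsim)
```

## The modelling problem

Functional graph models of protected-area networks link sites by the
actual or potential movements of one target species; network-wide
statements then require a battery of per-species graphs.
`econetsim` implements the similarity-based alternative: describe each
site by what it contains — its reported species, habitat types, or
land-cover classes — and link two sites when they are geographically
close enough for exchange *and* sufficiently alike for an exchange to
be ecologically meaningful. The package builds these graphs, evaluates
how well each variant concentrates the edges of single-species graphs
(the hit-rate analysis), compares graphs through rank correlations of
hit rates and of node indices, and extracts candidate relocation
sites.

The analysis rests on three assumptions worth making explicit:

* the composition tables are reliable presence inventories — absence
  of a code means absence of the feature, not a reporting gap (missing
  land-use data is handled separately by a site filter);
* within the distance threshold, geographical distance itself is not
  informative beyond the cut — edges are unweighted;
* similarity of reported composition is a usable proxy for habitat
  suitability when direct species–habitat suitability data are absent.

## Graph families and evaluation

All graphs share one node set (one node per site record; an
overlapping SPA/SCI designation contributes two records declared
zero-distance partners) and a distance threshold `d_max`
(default 30 km). The four families are the raw-distance graph
(`build_raw_distance()`), the single-species graph and its full-node
variant (`build_single_species()`), and the similarity-based graph
(`build_similarity_graph()`), which keeps the raw-distance edges with
similarity at least `s_min` (default 0.5). Construction guarantees,
asserted in the test suite, are that every similarity-based and full
single-species edge set is a subset of the raw-distance edge set and
that edge sets are nested along decreasing `s_min`.

Evaluation uses the hit rate `h/m` per species (`m` single-species
edges, `h` of them present in the similarity graph), the unweighted
average hit rate `R` across species, and the normalized hit rate
`R·n/|E|`, where `n` is the raw-distance edge count. Normalization by
relative density `|E|/n` removes the advantage a denser graph has by
chance: a graph whose edges were a uniform sample of raw-distance
edges has expected normalized hit rate 1, so values above 1 measure
genuine concentration of species co-occurrence edges.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `distance_threshold_km` | 30 | km | maximal linking distance; inclusive (`d ≤ t`) |
| `similarity_threshold` | 0.5 | — | minimal similarity score; inclusive (`s ≥ t`) |
| `sweep_levels` | 0.0–0.9 | — | levels of the edge-count sweep |
| recipes | 7 combinations | — | (dataset, mode, measure) per graph |

The seven default recipes are Jaccard on binary species, habitat and
land-use vectors, and cosine on occurrence-count and area-weighted
habitat and land-use vectors. Species vectors are binary only:
population-abundance data is too sparsely reported to support
non-binary species vectors, so the package rejects such recipes at
validation time.

Both thresholds are applied inclusively with exact double-precision
comparison and no tolerance; similarity scores are deterministic
functions of the input tables, so reruns are bit-reproducible and a
tolerance would only blur the stated contract ("equal or greater").
Whether a pair at exactly 30.000 km is linked is a convention; we
link it.

## The synthetic landscape generator

Regional protected-site extracts are not redistributable, so the
generator (`generate_landscape()`) supplies data with the statistical
structure the analysis assumes. Its design:

* **Geometry.** `n_sites` (default 100) uniform points in a square of
  side `region_extent_km` (default 135 km). Planar kilometre
  coordinates; no geodesy in synthetic mode, as projection error is
  irrelevant to the method under study. At these defaults roughly an
  eighth of site pairs fall within 30 km, giving a raw-distance graph
  of several hundred edges — the edge-count regime of a
  hundred-site regional network.
* **Dual designations.** A fraction `dual_designation_fraction`
  (default 0.10) of sites is emitted as SPA + SCI node pairs at
  identical coordinates, registered as mutual zero-distance partners,
  with identical composition rows. They make the zero-distance rule
  and its consequences (always-linked partner pairs in every graph)
  testable.
* **Habitat composition.** `n_archetypes` (default 6) archetype
  mixtures over the habitat-code pool — distinct sparse Dirichlet
  draws placed on a jittered grid so communities tile the region —
  are interpolated at each site with exponentially distance-decaying
  weights (`spatial_range_km`, default 25 km), then re-drawn per site
  from a Dirichlet centred on the interpolated field
  (`site_mix_concentration`, default 45) to add site-level
  idiosyncrasy. Nearby sites therefore have similar but not identical
  habitat mixes, with similarity decaying over tens of kilometres.
* **Reporting rule.** A code enters the composition table when it
  holds at least 2.5% of the site's mixture, mirroring inventory
  practice of recording types above a minimal areal share; patch
  counts beyond one per type are multinomial and areas follow the
  mixture with noise. Making presence a deterministic function of the
  mixture matters: if presence were itself sampled, binary Jaccard
  between equally-composed sites would be dominated by sampling noise
  and no similarity threshold could separate like from unlike sites.
* **Land use.** Site mixtures are drawn around one common regional
  land-use base (concentration 8), independent of habitat and
  species — real land-cover data is dominated by widespread classes
  and originates from a different programme than the biotic
  inventories. This yields land-use graphs of realistic density that
  carry no information about the biota, the null against which the
  habitat signal is judged.
* **Species occupancy.** Each of `n_species` (default 131) species
  belongs to a habitat community: its preference profile is a
  Dirichlet draw around one archetype mixture. Affinity of a site is
  the cosine between the site's *reported* habitat presence profile
  and the preference profile, standardized per species; occupancy is
  Bernoulli with `plogis(a_s + c_s · z)`. The per-species coupling
  `c_s` is the configured `habitat_species_coupling` times an Exp(1)
  multiplier — a specialist-to-generalist gradient, since uniform
  coupling produces assemblages in which every species carries the
  same signal and cross-graph rank correlations degenerate. The
  per-species intercept `a_s` is solved (logit-normal approximation)
  so that expected prevalence matches a log-odds target
  `prevalence_intercept + N(0,1)` regardless of coupling; prevalence
  would otherwise inflate with coupling. Standardizing the affinity
  is deliberate: raw cosine affinities span a narrow range, and a
  logistic on the raw scale cannot push occupancy probabilities
  toward 0/1 — yet near-deterministic occupancy is exactly what lets
  similar sites host similar species sets (with independent Bernoulli
  noise at prevalence p, the species-set Jaccard of two identically
  suitable sites is capped near p/(2−p)).
* **Missing data.** A fraction `missing_data_fraction` (default 0.03)
  of site records loses its land-use rows and is flagged; the
  pipeline's site filter excludes flagged sites, reproducing the
  usable-site accounting of a real regional extract.

With `habitat_species_coupling = 0`, occupancy is independent of
habitat: the generator then satisfies, and the tests verify, that
habitat-similarity and species-set-similarity of site pairs are
uncorrelated and that neither the habitat nor the land-use graph
systematically wins the evaluation.

**What the generator does not emulate:** real biogeography (species
ranges are community-shaped, not shaped by dispersal history),
polygon-level patch geometry (sites are points; boundary-distance mode
exists but default landscapes do not exercise it), reporting biases
that correlate across neighbouring sites, and abundance data. Passing
tests therefore show that the pipeline recovers planted structure of
this kind — not that any real network has such structure.

## Numerical conventions

* **Empty-versus-empty Jaccard** is defined as 0 with a warning: a
  site reporting nothing should not be linked to anything by
  similarity, and sparse synthetic data must not abort a run.
* **Zero-magnitude cosine** is undefined by construction; the
  pairwise wrapper stores `NA` and graph construction never links
  such pairs, so data gaps are distinguishable from true
  dissimilarity (similarity 0).
* **Betweenness** is summed over unordered pairs and normalized by
  `(N−1)(N−2)/2` over the full node count, unreachable pairs
  contributing 0. **Closeness** is component-local — the reciprocal
  mean shortest path to reachable nodes, 0 for isolates — so the
  disconnected graphs this analysis produces still yield finite
  values for every node. Different network tools normalize these
  two indices differently; within one graph the rank order, which is
  all the correlation analysis consumes, is unaffected.
* **Topological coefficient** of node `n`: the mean over nodes `m`
  sharing at least one neighbour with `n` of
  `(|common neighbours| + [n~m]) / k(n)`, 0 when nothing shares a
  neighbour with `n`. This shared-neighbour form, with the +1 bonus
  for a direct edge, is the convention of the network-analysis tools
  used in this literature, stated here explicitly because it is
  rarely printed.
* **Spearman correlations** use mid-ranks for ties with listwise
  deletion of undefined entries; fewer than 3 complete pairs or zero
  rank variance is an error for the scalar function, recorded as `NA`
  with a warning in correlation tables so a degenerate column cannot
  silently abort a pipeline run.
* **Species with no single-species edges** (`m = 0`) have undefined
  hit rates and are excluded from the average `R`; treating them as 0
  is available via `include_undefined = TRUE` but conflates "nothing
  to hit" with "missed everything".
* **Candidate sites** require the unoccupied condition: the candidate
  pair `(i, j)` has `i` in an occupied component, `j` unoccupied by
  the species, and `(i, j)` a similarity-graph edge. Reading only
  "outside this component" would admit occupied members of *other*
  components; relocation targets are sites the species does not
  already hold, so the stricter reading is implemented and oracled.
* **Determinism.** All generator randomness flows through one seeded
  RNG scope that restores the caller's RNG state; identical
  configuration and seed give byte-identical tables, and the pipeline
  manifest records an MD5 checksum per output file.

## Problem sizes in the test suite

The suite exercises the index implementations against a brute-force
oracle (Floyd–Warshall distances, shortest-path counts from adjacency
powers, explicit triangle and shared-neighbour counting) on 500 random
graphs of up to 8 nodes; structural invariants on 50 seeded 104-site
landscapes; the statistical signal-recovery property on 20 seeds at
the default (high) coupling and 20 at coupling 0; and the candidate
finder against an exhaustive pair scan on 100 random fixtures. These
sizes keep the default run in the low minutes while covering every
code path; all expected values are either hand-enumerable, oracle
recomputed, or arithmetic identities of reference table rows.

## Known limitations

* The signal-recovery comparison of hit-rate correlations is a
  statistic of a 131-species sample whose effective replication is
  the handful of habitat communities, not the species count; its
  seed-to-seed spread is therefore substantial, and an unlucky run of
  seeds can fall just short of the 90% margin the test asserts.
* Boundary-distance mode uses minimum vertex-to-segment distance;
  overlapping polygons are not detected as distance 0 unless declared
  as partners.
* The pipeline consumes precomputed composition tables; GIS
  intersection of site polygons with land-cover patches is out of
  scope, as is any visualization beyond text reports and GraphML
  export.
* Edge weights, species-specific distance thresholds, and
  budget-constrained edge-addition optimization are not modelled.
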