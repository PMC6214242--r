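Package: econetsim
Title: Similarity-Based Graph Models of Ecological Site Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds and evaluates graph models of protected-site networks
    (Natura 2000 style) from site attribute vectors. Sites are represented
    as binary, occurrence-count or area-weighted vectors over species,
    habitat or land-use code universes; Jaccard and cosine similarities
    thresholded jointly with a geographical distance threshold yield
    similarity-based graphs, which are scored against single-species
    graphs via hit rates and normalized hit rates, compared through
    Spearman correlations of hit rates and node-level network indices
    (degree, betweenness, closeness, clustering, topological coefficient),
    and mined for candidate relocation sites adjacent to occupied
    connected components. A seedable synthetic landscape generator with
    spatially autocorrelated habitat composition and habitat-coupled
    species occupancy supports testing without regional datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
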