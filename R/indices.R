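#' Node-level complex network indices
#'
#' Computes, for every node of an undirected simple graph, the five
#' indices used in the cross-graph correlation analysis:
#' \describe{
#'   \item{degree}{neighbour count `k`;}
#'   \item{betweenness}{fraction of shortest paths passing through the
#'     node, summed over unordered pairs of other nodes and normalized
#'     by `(N-1)(N-2)/2` with `N` the full node count; unreachable pairs
#'     contribute 0, so values stay in `[0, 1]` on disconnected graphs;}
#'   \item{closeness}{reciprocal of the mean shortest-path length from
#'     the node to the nodes it can reach (component-local; 0 for an
#'     isolated node), so disconnected graphs still yield finite values
#'     for every node;}
#'   \item{clustering}{local clustering coefficient
#'     `2 e_n / (k (k - 1))` with `e_n` the edges among neighbours; 0
#'     when `k < 2`;}
#'   \item{topological}{topological coefficient: the mean, over the
#'     nodes `m` sharing at least one neighbour with `n`, of
#'     `J(n, m) / k(n)`, where `J(n, m)` counts common neighbours plus 1
#'     if `(n, m)` is itself an edge; 0 when no node shares a neighbour
#'     with `n` or `k(n) = 0`.}
#' }
#' Degree, betweenness, closeness and clustering are delegated to
#' igraph under these conventions; the topological coefficient is
#' computed directly from its shared-neighbour definition.
#'
#' Absolute closeness/betweenness values depend on normalization
#' conventions and may differ across network tools; within one graph the
#' rank order — what the Spearman correlation analysis uses — does not.
#'
#' @param g an [eco_graph] (or igraph) undirected simple graph.
#' @return A `data.frame` with columns `node`, `degree`, `betweenness`,
#'   `closeness`, `clustering`, `topological`, one row per node.
#' @export
compute_indices <- function(g) {
  ig <- if (inherits(g, "eco_graph")) as_igraph(g) else g
  N <- igraph::vcount(ig)
  if (N == 0) {
    return(data.frame(node = character(0), degree = integer(0),
                      betweenness = numeric(0), closeness = numeric(0),
                      clustering = numeric(0), topological = numeric(0)))
  }
  nodes <- igraph::vertex_attr(ig, "name") %||% as.character(seq_len(N))
  deg <- as.integer(igraph::degree(ig))

  btw <- igraph::betweenness(ig, directed = FALSE)
  btw <- if (N > 2) btw / ((N - 1) * (N - 2) / 2) else rep(0, N)

  cls <- suppressWarnings(
    igraph::closeness(ig, mode = "all", normalized = TRUE)
  )
  cls[!is.finite(cls)] <- 0  # isolated nodes

  clu <- igraph::transitivity(ig, type = "localundirected",
                              isolates = "zero")

  A <- as.matrix(igraph::as_adjacency_matrix(ig, sparse = TRUE))
  topo <- topological_coefficient(A, deg)

  data.frame(node = nodes, degree = deg, betweenness = as.numeric(btw),
             closeness = as.numeric(cls), clustering = as.numeric(clu),
             topological = topo, stringsAsFactors = FALSE)
}

# Shared-neighbour topological coefficient from an adjacency matrix.
# common[n, m] = |common neighbours|; J adds 1 where (n, m) is an edge.
topological_coefficient <- function(A, deg = rowSums(A)) {
  N <- nrow(A)
  if (N == 0) return(numeric(0))
  common <- A %*% A
  J <- common + A
  shares <- common > 0
  diag(shares) <- FALSE
  out <- numeric(N)
  for (n in seq_len(N)) {
    Sn <- which(shares[n, ])
    if (length(Sn) == 0 || deg[n] == 0) {
      out[n] <- 0
    } else {
      out[n] <- mean(J[n, Sn]) / deg[n]
    }
  }
  out
}

#' Write a node index table as CSV
#' @param tab `data.frame` from [compute_indices].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_index_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
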