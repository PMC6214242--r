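# independent brute-force oracles, deliberately written along different
# routes than the implementation

# all-pairs shortest-path lengths by Floyd-Warshall
oracle_dists <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# numbers of shortest paths from powers of the adjacency matrix:
# a minimal-length walk cannot revisit a vertex, so sigma[s, t] equals
# the (s, t) entry of A^d with d the shortest-path length
oracle_sigma_powers <- function(A) {
  n <- nrow(A)
  P <- vector("list", max(n - 1, 1))
  P[[1]] <- A
  if (n > 2) for (k in 2:(n - 1)) P[[k]] <- P[[k - 1]] %*% A
  P
}

oracle_indices <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  D <- oracle_dists(A)
  P <- oracle_sigma_powers(A)
  sig <- function(i, j) {
    d <- D[i, j]
    if (d == 0) 1 else P[[d]][i, j]
  }
  btw <- numeric(n)
  if (n > 2) {
    for (v in seq_len(n)) {
      acc <- 0
      for (s in seq_len(n - 1)) for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(D[s, t])) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          acc <- acc + sig(s, v) * sig(v, t) / sig(s, t)
        }
      }
      btw[v] <- acc / ((n - 1) * (n - 2) / 2)
    }
  }
  cls <- vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, 0)
  A3 <- if (n > 1) A %*% A %*% A else A
  clu <- vapply(seq_len(n), function(v) {
    k <- deg[v]
    if (k < 2) 0 else A3[v, v] / (k * (k - 1))
  }, 0)
  topo <- vapply(seq_len(n), function(v) {
    if (deg[v] == 0) return(0)
    js <- numeric(0)
    for (m in seq_len(n)) {
      if (m == v) next
      shared <- sum(A[v, ] == 1 & A[m, ] == 1)
      if (shared > 0) js <- c(js, shared + (A[v, m] == 1))
    }
    if (length(js) == 0) 0 else mean(js) / deg[v]
  }, 0)
  data.frame(degree = deg, betweenness = btw, closeness = cls,
             clustering = clu, topological = topo)
}

# rank-then-Pearson route for Spearman with mid-ranks
oracle_spearman <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  ra <- rank(a[ok], ties.method = "average")
  rb <- rank(b[ok], ties.method = "average")
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# exhaustive candidate scan: all (i, j) site pairs against the four
# conditions (i in the component, j in the universe, j unoccupied,
# (i, j) an edge of the similarity graph)
oracle_candidates <- function(species_graph, sim_graph) {
  occupied <- species_graph$nodes
  V <- sim_graph$nodes
  sim_keys <- paste(sim_graph$edges$from, sim_graph$edges$to, sep = "\r")
  has_edge <- function(a, b) {
    paste(min(a, b), max(a, b), sep = "\r") %in% sim_keys
  }
  # components by repeated neighbourhood expansion
  comp_of <- stats::setNames(rep(NA_integer_, length(occupied)), occupied)
  cid <- 0L
  adj <- split(c(species_graph$edges$to, species_graph$edges$from),
               c(species_graph$edges$from, species_graph$edges$to))
  for (v in occupied) {
    if (!is.na(comp_of[v])) next
    cid <- cid + 1L
    frontier <- v
    while (length(frontier) > 0) {
      comp_of[frontier] <- cid
      nxt <- unique(unlist(adj[frontier]))
      frontier <- nxt[!is.na(nxt) & is.na(comp_of[nxt])]
    }
  }
  lapply(seq_len(cid), function(k) {
    Vp <- sort(occupied[comp_of == k])
    cand <- expand.grid(i = Vp, j = V, stringsAsFactors = FALSE)
    keep <- !(cand$j %in% occupied) &
      mapply(has_edge, cand$i, cand$j)
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[order(cand$i, cand$j), , drop = FALSE]
    rownames(cand) <- NULL
    list(component = Vp, candidates = cand)
  })
}
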