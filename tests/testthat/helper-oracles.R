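# Independent brute-force oracles used to cross-check the package's graph
# metrics. Deliberately naive implementations: exhaustive loops, no shared
# code with R/graphnet.R.

# Per-node clustering coefficient by explicit neighbour-pair counting.
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]]) t_i <- t_i + 1
    cc[i] <- 2 * t_i / (k * (k - 1))
  }
  cc
}

# All-pairs shortest paths by Floyd-Warshall.
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# CPL with the package's stated conventions, recomputed independently:
# per-node mean over reachable partners, isolated nodes contribute 0,
# edgeless graph is NA.
oracle_cpl <- function(adj) {
  D <- oracle_floyd_warshall(adj)
  n <- nrow(D)
  if (n < 2 || !any(adj)) return(NA_real_)
  per <- sapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else mean(d)
  })
  mean(per)
}

# Random symmetric adjacency matrix (no self loops).
random_adjacency <- function(n, p) {
  a <- matrix(FALSE, n, n)
  a[upper.tri(a)] <- stats::runif(n * (n - 1) / 2) < p
  a | t(a)
}

# Adjacency matrix of 6-node graph number `code` (bits fill the upper
# triangle column-wise).
graph6_from_code <- function(code, ut_idx) {
  a <- matrix(FALSE, 6, 6)
  a[ut_idx] <- as.logical(bitwAnd(code, 2^(0:14)))
  a | t(a)
}
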