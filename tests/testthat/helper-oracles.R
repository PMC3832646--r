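# Independent oracles used to cross-check the package's fast paths.

# Floyd-Warshall all-pairs shortest paths from the adjacency matrix,
# independent of igraph's BFS.
fw_dist_oracle <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

# Brute-force f-Wiener: explicit sum over all unordered pairs, no distance
# tabulation involved.
brute_force_wf <- function(g, f) {
  D <- fw_dist_oracle(g)
  sum(f$fun(D[upper.tri(D)]))
}

# Pair-counting adjusted Rand index (Hubert-Arabie via the four pair
# categories), independent of the contingency-table route.
ari_pair_oracle <- function(a, b) {
  ut <- upper.tri(diag(length(a)))
  sa <- outer(a, a, "==")[ut]
  sb <- outer(b, b, "==")[ut]
  n11 <- sum(sa & sb); n00 <- sum(!sa & !sb)
  n10 <- sum(sa & !sb); n01 <- sum(!sa & sb)
  den <- (n00 + n01) * (n01 + n11) + (n00 + n10) * (n10 + n11)
  if (den == 0) return(1)
  2 * (n00 * n11 - n01 * n10) / den
}

# Random connected graph for property tests.
rand_connected <- function(n, p = NULL, seed = NULL) {
  if (is.null(p)) p <- min(1, max(0.3, 2 * log(n) / n))
  er_connected(n, p, seed = seed)
}

# Uniform random labeled tree via a random Prüfer sequence.
rand_tree <- function(n) {
  code <- if (n > 2) sample.int(n, n - 2L, replace = TRUE) else integer(0)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::add_edges(g, prufer_to_edges(code, n))
}
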