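## Seeded random-network generators, all conditioned on connectivity.

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Derive reproducible child seeds from one base seed
#'
#' Expands a single base seed into `k` independent child seeds (integers in
#' `[1, 2^31 - 2]`) so that any single generated graph can be reproduced in
#' isolation.
#'
#' @param seed base seed (integer).
#' @param k number of child seeds.
#' @return integer vector of length `k`.
#' @export
derive_seeds <- function(seed, k) {
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max - 1L, k))
}

#' Connected Erdős–Rényi random graph
#'
#' Draws G(n, p) graphs — each of the `choose(n, 2)` edges present
#' independently with probability `p` — and returns the first connected
#' draw.
#'
#' @param n number of nodes.
#' @param p edge probability in (0, 1].
#' @param seed optional integer seed; when given, the result is a pure
#'   function of `(n, p, seed)` and the caller's RNG state is untouched.
#' @param max_retries attempts before giving up on connectivity.
#' @return a connected undirected simple igraph graph on `n` nodes.
#' @examples
#' g <- er_connected(30, 0.2, seed = 1)
#' is_connected(g)
#' @export
er_connected <- function(n, p, seed = NULL, max_retries = 1000L) {
  n <- check_order(n)
  stopifnot(p > 0, p <= 1)
  with_opt_seed(seed, {
    pairs <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
    for (i in seq_len(max_retries)) {
      keep <- stats::runif(nrow(pairs)) < p
      g <- igraph::make_empty_graph(n, directed = FALSE)
      g <- igraph::add_edges(g, t(pairs[keep, , drop = FALSE]))
      if (is_connected(g)) return(g)
    }
    stop(sprintf("no connected G(n = %d, p = %g) draw in %d attempts",
                 n, p, max_retries), call. = FALSE)
  })
}

#' Preferential-attachment (scale-free) random graph
#'
#' Growth model: starting from a single node, each arriving node attaches
#' `m` edges (fewer while fewer than `m` nodes exist) to distinct existing
#' nodes chosen with probability proportional to degree + 1; the +1 keeps
#' the isolated seed node reachable. The result is connected by
#' construction and, for `m = 1`, a tree.
#'
#' @param n number of nodes.
#' @param m edges added per arriving node, `1 <= m < n`.
#' @param seed optional integer seed.
#' @return a connected undirected simple igraph graph with
#'   `sum(pmin(m, 1:(n-1)))` edges.
#' @examples
#' igraph::ecount(preferential_attachment(20, 3, seed = 7)) # 54
#' @export
preferential_attachment <- function(n, m, seed = NULL) {
  n <- check_order(n)
  m <- as.integer(m)
  stopifnot(m >= 1L, m < n)
  with_opt_seed(seed, {
    n_edges <- sum(pmin(m, seq_len(n - 1L)))
    edges <- matrix(0L, 2L, n_edges)
    deg <- integer(n)
    pos <- 0L
    for (v in 2:n) {
      m_eff <- min(m, v - 1L)
      targets <- if (m_eff == v - 1L) seq_len(v - 1L)
                 else sample.int(v - 1L, m_eff, prob = deg[seq_len(v - 1L)] + 1)
      edges[, pos + seq_len(m_eff)] <- rbind(v, targets)
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m_eff
      pos <- pos + m_eff
    }
    g <- igraph::make_empty_graph(n, directed = FALSE)
    igraph::add_edges(g, edges)
  })
}

#' 3-D geometric random graph
#'
#' Places `n` points uniformly and independently in the unit cube, ranks
#' all `choose(n, 2)` pairwise Euclidean distances in ascending order, and
#' connects the closest `floor(q * choose(n, 2))` pairs (ties at the cutoff
#' broken by pair index order, pairs enumerated column-major over the lower
#' triangle). Point sets are resampled until the network is connected.
#'
#' @param n number of nodes.
#' @param q fraction of closest pairs to connect, in (0, 1];
#'   `q * choose(n, 2)` must be at least `n - 1` for connectivity to be
#'   possible.
#' @param seed optional integer seed.
#' @param max_retries attempts before giving up on connectivity.
#' @return a connected undirected simple igraph graph with exactly
#'   `floor(q * choose(n, 2))` edges.
#' @examples
#' igraph::ecount(geometric3d(100, 0.05, seed = 3)) # 247
#' @export
geometric3d <- function(n, q, seed = NULL, max_retries = 1000L) {
  n <- check_order(n)
  stopifnot(q > 0, q <= 1)
  n_pairs <- choose(n, 2)
  k <- floor(q * n_pairs)
  if (k < n - 1L) {
    stop(sprintf("q = %g keeps only %d edges; %d nodes need at least %d",
                 q, k, n, n - 1L), call. = FALSE)
  }
  # lower-triangle pairs in column-major order: the storage order of dist()
  pairs <- which(lower.tri(matrix(0L, n, n)), arr.ind = TRUE)
  with_opt_seed(seed, {
    for (i in seq_len(max_retries)) {
      pts <- matrix(stats::runif(3L * n), ncol = 3L)
      d <- as.vector(dist(pts))
      closest <- order(d, seq_along(d))[seq_len(k)]
      g <- igraph::make_empty_graph(n, directed = FALSE)
      g <- igraph::add_edges(g, t(pairs[closest, , drop = FALSE]))
      if (is_connected(g)) return(g)
    }
    stop(sprintf("no connected geometric graph (n = %d, q = %g) in %d attempts",
                 n, q, max_retries), call. = FALSE)
  })
}
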