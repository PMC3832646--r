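## Characteristic vectors, Ward clustering, dendrogram cuts, adjusted Rand.

#' Characteristic index vector of a graph
#'
#' Evaluates each function of the catalog on the graph, either raw
#' (`f_wiener` values) or normalized (`normalized_index` values in
#' `[0, 1]`). These vectors are the features on which network collections
#' are clustered; in raw form they are dominated by network size, in
#' normalized form they reflect topology alone.
#'
#' @param g a connected undirected simple igraph graph.
#' @param catalog list of [index_function()]s, default [builtin_catalog()].
#' @param normalized use the normalized index?
#' @param domain normalization domain, `"graphs"` or `"trees"` (trees only
#'   for tree inputs).
#' @return named numeric vector, one entry per catalog function.
#' @examples
#' characteristic_vector(make_special("complete", 10), normalized = TRUE)
#' @export
characteristic_vector <- function(g, catalog = builtin_catalog(),
                                  normalized = FALSE,
                                  domain = c("graphs", "trees")) {
  domain <- match.arg(domain)
  ds <- distance_summary(g)
  vals <- if (normalized) {
    vapply(catalog, function(f) normalized_index(g, f, domain), numeric(1))
  } else {
    vapply(catalog, function(f) f_wiener(ds, f), numeric(1))
  }
  names(vals) <- vapply(catalog, `[[`, "", "name")
  vals
}

#' Characteristic vectors for a collection of graphs
#'
#' @param graphs list of connected igraph graphs.
#' @inheritParams characteristic_vector
#' @return numeric matrix, one row per graph, one column per catalog
#'   function.
#' @export
characteristic_matrix <- function(graphs, catalog = builtin_catalog(),
                                  normalized = FALSE,
                                  domain = c("graphs", "trees")) {
  domain <- match.arg(domain)
  t(vapply(graphs, characteristic_vector, numeric(length(catalog)),
           catalog = catalog, normalized = normalized, domain = domain))
}

#' Ward hierarchical clustering of characteristic vectors
#'
#' Agglomerative clustering under Ward's minimum-variance criterion on
#' Euclidean distances (the Lance–Williams update on squared distances, as
#' implemented by [stats::hclust()] method `"ward.D2"`). Merge heights are
#' non-decreasing. No feature standardization is applied: scale domination
#' of raw vectors by the largest index is exactly the phenomenon the
#' normalized vectors are designed to remove, and normalized entries
#' already share the `[0, 1]` scale.
#'
#' @param x numeric matrix of feature vectors (rows = items), or a list of
#'   equal-length numeric vectors.
#' @return an object of class [stats::hclust].
#' @examples
#' ward_linkage(rbind(c(0, 0), c(1, 0), c(10, 0)))
#' @export
ward_linkage <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) > 1L) {
      stop("all feature vectors must have equal length", call. = FALSE)
    }
    x <- do.call(rbind, x)
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
}

#' Cut a dendrogram into k clusters
#'
#' @param tree an [stats::hclust] tree (as from [ward_linkage()]).
#' @param k number of clusters, `1 <= k <= n`.
#' @return integer vector of cluster labels in `1..k`, one per item.
#' @export
cut_k <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n) {
    stop(sprintf("`k` must be in 1..%d", n), call. = FALSE)
  }
  unname(stats::cutree(tree, k = k))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement, computed from the contingency
#' table of the two labelings:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}{M - E}} with
#' \eqn{E = \sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} / \binom{n}{2}} and
#' \eqn{M = \frac12\left(\sum_i \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right)}.
#' Equals 1 for identical partitions, has expectation 0 under random
#' labeling, and is symmetric in its arguments. In the degenerate case
#' where both partitions are trivial (denominator 0: both all-singletons or
#' both one block) the index is defined as 1 if the partitions are
#' identical and 0 otherwise.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in `[-1, 1]`.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)) # 1
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  n <- length(a)
  if (n < 2L) stop("need at least 2 items", call. = FALSE)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  e <- sum_a * sum_b / choose(n, 2)
  m <- (sum_a + sum_b) / 2
  if (m == e) {
    # both partitions trivial in the same way; agreement is all-or-nothing
    return(if (sum_ij == m && sum_a == sum_b) 1 else 0)
  }
  (sum_ij - e) / (m - e)
}

#' ARI of uniformly random cluster assignments against a fixed truth
#'
#' Monte-Carlo baseline: each replicate assigns every item independently
#' and uniformly to one of `k` clusters and scores it against `truth`.
#' Under this null the ARI has mean 0; its spread quantifies how much
#' apparent agreement chance alone produces.
#'
#' @param truth reference label vector.
#' @param k number of clusters to assign at random.
#' @param reps number of replicates.
#' @param seed optional integer seed.
#' @return numeric vector of `reps` ARI values.
#' @examples
#' x <- random_clustering_ari(rep(1:3, each = 10), 3, reps = 100, seed = 1)
#' mean(x)
#' @export
random_clustering_ari <- function(truth, k, reps = 10000L, seed = NULL) {
  n <- length(truth)
  with_opt_seed(seed, {
    vapply(seq_len(reps), function(i) {
      adjusted_rand_index(truth, sample.int(k, n, replace = TRUE))
    }, numeric(1))
  })
}
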