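## The f-Wiener index engine.

#' The f-Wiener index of a connected graph
#'
#' Computes \eqn{W_f(G) = \sum_{\{u,v\}} f(d(u,v))}, the sum over all
#' unordered pairs of distinct nodes of `f` applied to their shortest-path
#' distance. Specializations: `f(k) = k` is the classical Wiener index,
#' `f(k) = 1/k` the Harary index, `f(k) = (k^2+k)/2` the hyper-Wiener index,
#' `f(k) = k^alpha` the generalized Wiener index and `f(k) = q^k` the Hosoya
#' polynomial evaluated at `q`.
#'
#' The sum is accumulated from the distance distribution as
#' \eqn{\sum_k D_k f(k)} where \eqn{D_k} counts pairs at distance `k`, so a
#' graph on `n` nodes costs one BFS per node plus O(diameter) accumulation.
#'
#' @param g a connected undirected simple igraph graph with at least 2
#'   nodes, or a precomputed [distance_summary()].
#' @param f an [index_function()] (or a name accepted by
#'   [lookup_function()]).
#' @return the index value, a numeric scalar.
#' @examples
#' f_wiener(make_special("path", 4), lookup_function("wiener")) # 10
#' @export
f_wiener <- function(g, f) {
  if (is.character(f)) f <- lookup_function(f)
  stopifnot(inherits(f, "index_function"))
  ds <- if (inherits(g, "distance_summary")) g else distance_summary(g)
  if (ds$node_count < 2L) {
    stop("f-Wiener index requires at least 2 nodes", call. = FALSE)
  }
  k <- seq_along(ds$pair_counts)
  sum(ds$pair_counts * f$fun(k))
}

#' Evaluate the Hosoya (Wiener) polynomial
#'
#' \eqn{H_G(q) = \sum_k D_k q^k} where \eqn{D_k} is the number of node pairs
#' at distance `k`. `H_G(1)` equals the number of pairs `choose(n, 2)` and
#' `H_G'(1)` equals the Wiener index.
#'
#' @param g a connected undirected simple igraph graph, or a
#'   [distance_summary()].
#' @param q numeric evaluation point (may be a vector).
#' @return numeric value(s) of the polynomial at `q`.
#' @examples
#' hosoya_eval(make_special("complete", 4), 0.5) # 3
#' @export
hosoya_eval <- function(g, q) {
  ds <- if (inherits(g, "distance_summary")) g else distance_summary(g)
  k <- seq_along(ds$pair_counts)
  vapply(q, function(qi) sum(ds$pair_counts * qi^k), numeric(1))
}

#' Named Wiener-type indices
#'
#' Convenience dispatcher: computes the descriptor selected by name via
#' [f_wiener()] with the corresponding catalog function.
#'
#' @param g a connected undirected simple igraph graph.
#' @param name `"wiener"`, `"harary"`, `"hyper_wiener"`, or
#'   `"generalized:ALPHA"` (e.g. `"generalized:-1"`).
#' @return the index value, a numeric scalar.
#' @examples
#' named_index(make_special("star", 5), "wiener") # 16
#' @export
named_index <- function(g, name) {
  f_wiener(g, lookup_function(name))
}
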