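## Sharp extremal values of W_f over connected graphs and trees, and the
## normalized index N_f in [0, 1].

#' Closed-form f-Wiener values of the extremal families
#'
#' The three families attaining the sharp bounds have explicit index values:
#' \describe{
#'   \item{path}{\eqn{W_f(P_n) = \sum_{k=1}^{n-1} (n - k) f(k)}}
#'   \item{star}{\eqn{W_f(S_n) = (n-1) f(1) + \binom{n-1}{2} f(2)}}
#'   \item{complete}{\eqn{W_f(K_n) = \binom{n}{2} f(1)}}
#' }
#' Each equals `f_wiener(make_special(family, n), f)` exactly.
#'
#' @param n number of nodes, `n >= 2`.
#' @param f an [index_function()] or a name accepted by
#'   [lookup_function()].
#' @return numeric scalar.
#' @examples
#' path_value(5, "wiener")     # 20
#' star_value(5, "wiener")     # 16
#' complete_value(5, "wiener") # 10
#' @export
path_value <- function(n, f) {
  f <- as_index_function(f)
  n <- check_order(n)
  k <- seq_len(n - 1L)
  sum((n - k) * f$fun(k))
}

#' @rdname path_value
#' @export
star_value <- function(n, f) {
  f <- as_index_function(f)
  n <- check_order(n)
  (n - 1) * f$fun(1L) + choose(n - 1, 2) * f$fun(2L)
}

#' @rdname path_value
#' @export
complete_value <- function(n, f) {
  f <- as_index_function(f)
  n <- check_order(n)
  choose(n, 2) * f$fun(1L)
}

as_index_function <- function(f) {
  if (is.character(f)) f <- lookup_function(f)
  stopifnot(inherits(f, "index_function"))
  f
}

check_order <- function(n, min = 2L) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < min) {
    stop(sprintf("`n` must be an integer >= %d", min), call. = FALSE)
  }
  n
}

#' Sharp extremal values of the f-Wiener index
#'
#' Over all connected graphs on `n` nodes, a non-decreasing `f` gives
#' \eqn{W_f(K_n) \le W_f(G) \le W_f(P_n)}, with the lower bound attained
#' only by the complete graph and the upper bound only by the path. Over
#' trees the star replaces the complete graph:
#' \eqn{W_f(S_n) \le W_f(T) \le W_f(P_n)}. For non-increasing `f` the same
#' statements hold with minimum and maximum exchanged (replace `f` by
#' `-f`), so the path and the complete graph (resp. star) are the extremal
#' families for every monotone `f`.
#'
#' @param n number of nodes; `n >= 3` for graphs, `n >= 4` for trees (below
#'   these orders the extremal families coincide and the range degenerates).
#' @param f an [index_function()] or name.
#' @param domain `"graphs"` (all simple connected graphs) or `"trees"`.
#' @return an object of class `extremal_pair`: list with `min_value`,
#'   `max_value`, `minimizer_family`, `maximizer_family`, `domain`, `n`.
#' @examples
#' extremes(5, "wiener", "graphs") # min 10 (complete), max 20 (path)
#' @export
extremes <- function(n, f, domain = c("graphs", "trees")) {
  domain <- match.arg(domain)
  f <- as_index_function(f)
  n <- check_order(n, min = if (domain == "graphs") 3L else 4L)
  pv <- path_value(n, f)
  dv <- if (domain == "graphs") complete_value(n, f) else star_value(n, f)
  dense_family <- if (domain == "graphs") "complete" else "star"
  if (pv == dv) {
    stop(sprintf("degenerate index function '%s': extremal values coincide at n = %d",
                 f$name, n), call. = FALSE)
  }
  if (f$direction == "non-decreasing") {
    res <- list(min_value = dv, max_value = pv,
                minimizer_family = dense_family, maximizer_family = "path")
  } else {
    res <- list(min_value = pv, max_value = dv,
                minimizer_family = "path", maximizer_family = dense_family)
  }
  structure(c(res, list(domain = domain, n = n, function_name = f$name)),
            class = "extremal_pair")
}

#' @export
print.extremal_pair <- function(x, ...) {
  cat(sprintf("W_%s over %s on %d nodes: [%g at %s, %g at %s]\n",
              x$function_name, x$domain, x$n, x$min_value,
              x$minimizer_family, x$max_value, x$maximizer_family))
  invisible(x)
}

#' Normalized f-Wiener index
#'
#' Affine rescaling of \eqn{W_f} to \eqn{[0,1]} using the sharp extremal
#' values over graphs or trees of the same node count:
#' \deqn{N_f(G) = \frac{W_f(G) - W_f(P_n)}{W_f(X_n) - W_f(P_n)}}
#' where \eqn{X_n} is the complete graph (graphs domain) or the star (trees
#' domain). The orientation is fixed so that the path maps to 0 and the
#' densest family to 1 for every monotone `f`, regardless of its direction:
#' 0 reads "path-like", 1 reads "complete-like" (or "star-like" among
#' trees). Because the path value can be either the maximum or the minimum
#' depending on `f`'s direction, this is deliberately not the naive
#' `(W - min)/(max - min)`.
#'
#' Values are clamped to `[0, 1]` only against floating-point slop of at
#' most `1e-12` of the normalization range; a genuine violation (which would
#' contradict the sharp bounds) raises an error.
#'
#' @param g a connected undirected simple igraph graph; with
#'   `domain = "trees"` it must be a tree.
#' @param f an [index_function()] or name.
#' @param domain normalize against all connected `"graphs"` or all
#'   `"trees"` of the same order.
#' @return the normalized value, a numeric scalar in `[0, 1]`.
#' @examples
#' normalized_index(make_special("path", 5), "wiener", "trees") # 0
#' normalized_index(make_special("star", 5), "wiener", "trees") # 1
#' normalized_index(make_special("star", 5), "wiener", "graphs") # 0.4
#' @export
normalized_index <- function(g, f, domain = c("graphs", "trees")) {
  domain <- match.arg(domain)
  f <- as_index_function(f)
  assert_graph(g)
  n <- igraph::vcount(g)
  check_order(n, min = if (domain == "graphs") 3L else 4L)
  if (domain == "trees" && !is_tree_graph(g)) {
    stop("tree-domain normalization requested for a graph that is not a tree",
         call. = FALSE)
  }
  w <- f_wiener(g, f)
  a <- path_value(n, f)
  b <- if (domain == "graphs") complete_value(n, f) else star_value(n, f)
  if (a == b) {
    stop(sprintf("degenerate normalization for '%s' at n = %d", f$name, n),
         call. = FALSE)
  }
  val <- (w - a) / (b - a)
  slop <- 1e-12
  if (val < -slop || val > 1 + slop) {
    stop(sprintf("normalized index %g outside [0,1]: input violates the sharp bounds",
                 val), call. = FALSE)
  }
  min(max(val, 0), 1) + 0   # + 0 folds IEEE -0 into 0
}

#' Maximum f-Wiener index under a maximum-degree constraint
#'
#' Among trees on `n` nodes with maximum degree exactly `Delta`, a
#' non-decreasing `f` attains its largest index value on the broom
#' `broom(n, Delta - 1)` (a path with `Delta - 1` extra pendant leaves at
#' one end). `Delta = 2` recovers the path and `Delta = n - 1` the star,
#' consistent with the unconstrained extremes. For `domain = "graphs"` the
#' same broom value is returned: adding edges can only shrink distances, so
#' the constrained maximum over graphs is attained by a tree; this
#' graph-domain claim is certified empirically by exhaustive enumeration at
#' small `n` (see [verify_extremal()]) rather than by a closed-form
#' argument.
#'
#' @param n number of nodes.
#' @param Delta maximum degree, `2 <= Delta <= n - 1`.
#' @param f a non-decreasing [index_function()] or name.
#' @param domain `"trees"` or `"graphs"`.
#' @return list with `value` (the maximal index) and `extremal_graph` (the
#'   broom attaining it).
#' @examples
#' degree_constrained_max(5, 4, "wiener")$value # 16, the star
#' @export
degree_constrained_max <- function(n, Delta, f,
                                   domain = c("trees", "graphs")) {
  domain <- match.arg(domain)
  f <- as_index_function(f)
  n <- check_order(n, min = 3L)
  Delta <- as.integer(Delta)
  if (length(Delta) != 1L || is.na(Delta) || Delta < 2L || Delta > n - 1L) {
    stop("`Delta` must satisfy 2 <= Delta <= n - 1", call. = FALSE)
  }
  if (f$direction != "non-decreasing") {
    stop("degree-constrained maximum is stated for non-decreasing f",
         call. = FALSE)
  }
  broom <- make_special("broom", n, param = Delta - 1L)
  list(value = f_wiener(broom, f), extremal_graph = broom)
}

#' Smallest node-count excess making some star closer than a larger path
#'
#' How strongly does network size mask topology in the raw Wiener index?
#' Compare two paths \eqn{P_n} and \eqn{P_m} (`m > n`) with the stars
#' \eqn{S_k}: once `m` exceeds `n` by a modest percentage, some star of at
#' most `m` nodes has a Wiener index strictly closer to \eqn{W(P_n)} than
#' \eqn{W(P_m)} is — a star then looks more like the small path than the
#' larger path does. Using the closed forms
#' \eqn{W(P_j) = j(j^2-1)/6} and \eqn{W(S_k) = (k-1)^2}, this function
#' finds, by exhaustive search, the smallest integer percentage `c` such
#' that for every `n` in `n_range` and every `m` with
#' `ceiling(n (1 + c/100)) <= m <= 2n` there is a star \eqn{S_k},
#' `3 <= k <= m`, with
#' \eqn{|W(S_k) - W(P_n)| < |W(P_m) - W(P_n)|}. Asymptotically the
#' threshold is governed by \eqn{2^{1/3} - 1 \approx 26\%}.
#'
#' @param n_range integer vector of smaller-path orders to test.
#' @return the smallest integer percentage, with attribute `per_n` giving
#'   for each `n` the smallest admissible `m`.
#' @examples
#' star_proximity_threshold(10:60)
#' @export
star_proximity_threshold <- function(n_range = 10:200) {
  n_range <- as.integer(n_range)
  stopifnot(all(n_range >= 3L))
  m_max <- 2L * max(n_range)
  wp <- c(0, vapply(2:m_max, function(j) path_value(j, "wiener"),
                    numeric(1)))
  ws <- (seq_len(m_max) - 1)^2              # star_value(k, wiener)
  m_star <- vapply(n_range, function(n) {
    m_cand <- (n + 1L):(2L * n)
    # best star error min_{3<=k<=m} |W(S_k) - W(P_n)|, nonincreasing in m
    best_err <- cummin(abs(ws[3:(2L * n)] - wp[n]))[m_cand - 2L]
    ok <- best_err < wp[m_cand] - wp[n]
    m_cand[which(ok)[1]]
  }, integer(1))
  # smallest c with ceiling(n(1 + c/100)) >= m for every n
  c_n <- ceiling(100 * (m_star - 1L - n_range) / n_range + 1e-9)
  structure(max(0L, c_n), per_n = data.frame(n = n_range, m = m_star))
}

#' Explicit extremal bounds for the named indices
#'
#' Specializes the sharp bounds to the classical descriptors. For the
#' Wiener index over graphs, for instance, the pair is
#' \eqn{(n(n-1)/2,\; n(n+1)(n-1)/6)}; over trees the lower endpoint becomes
#' the star value \eqn{(n-1)^2}. Exactly equal to [extremes()] with the
#' corresponding catalog function.
#'
#' @param n number of nodes.
#' @param index_name `"wiener"`, `"harary"`, `"hyper_wiener"` or
#'   `"generalized:ALPHA"`.
#' @param domain `"graphs"` or `"trees"`.
#' @return an `extremal_pair`.
#' @examples
#' corollary_bounds(5, "wiener", "graphs") # (10, 20)
#' @export
corollary_bounds <- function(n, index_name, domain = c("graphs", "trees")) {
  extremes(n, lookup_function(index_name), match.arg(domain))
}
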