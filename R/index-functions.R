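## Catalog of monotone functions f defining f-Wiener indices.

#' Create an index function
#'
#' An index function is a monotone function `f` on the positive integers
#' together with its declared monotonicity direction; every choice of `f`
#' induces the descriptor \eqn{W_f(G) = \sum_{\{u,v\}} f(d(u,v))}.
#' Monotonicity in the declared direction is checked on construction by
#' evaluating `f` at `k = 1..1000`.
#'
#' `f` is only ever evaluated at distances `k >= 1` (pairs of distinct
#' nodes), so its value at 0 is irrelevant.
#'
#' @param name short identifier, e.g. `"wiener"` or `"power:2"`.
#' @param fun vectorized function of a positive integer distance.
#' @param direction `"non-decreasing"` or `"non-increasing"`.
#' @param params optional named list of numeric parameters.
#' @return an object of class `index_function` with elements `name`, `fun`,
#'   `direction`, `params`.
#' @examples
#' f <- index_function("cube", function(k) k^3, "non-decreasing")
#' f$fun(2)
#' @export
index_function <- function(name, fun, direction = c("non-decreasing",
                                                    "non-increasing"),
                           params = list()) {
  direction <- match.arg(direction)
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  v <- fun(1:1000)
  if (length(v) != 1000L || anyNA(v) || any(!is.finite(v))) {
    stop(sprintf("index function '%s' must be finite and vectorized on 1..1000",
                 name), call. = FALSE)
  }
  dv <- diff(v)
  ok <- if (direction == "non-decreasing") all(dv >= 0) else all(dv <= 0)
  if (!ok) {
    stop(sprintf("index function '%s' is not %s on 1..1000", name, direction),
         call. = FALSE)
  }
  structure(list(name = name, fun = fun, direction = direction,
                 params = params),
            class = "index_function")
}

#' @export
print.index_function <- function(x, ...) {
  cat(sprintf("Index function '%s' (%s); f(1..4) = %s\n", x$name,
              x$direction, paste(signif(x$fun(1:4), 4), collapse = ", ")))
  invisible(x)
}

is_strictly_monotone <- function(f, upto) {
  all(diff(f$fun(seq_len(upto))) != 0)
}

#' Power-family index function \eqn{f(k) = k^\alpha}
#'
#' The generalized Wiener family: `alpha = 1` gives the Wiener index,
#' `alpha = -1` the Harary index. `alpha = 0` is rejected because a constant
#' `f` makes every graph's index equal and normalization degenerate.
#'
#' @param alpha nonzero real exponent.
#' @return an `index_function`, non-decreasing iff `alpha > 0`.
#' @examples
#' power_function(-1)$fun(2) # 0.5
#' @export
power_function <- function(alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha == 0) {
    stop("alpha = 0 gives a constant function; normalization would be degenerate",
         call. = FALSE)
  }
  force(alpha)
  index_function(paste0("power:", format(alpha)),
                 function(k) k^alpha,
                 if (alpha > 0) "non-decreasing" else "non-increasing",
                 params = list(alpha = alpha))
}

#' Geometric-family index function \eqn{f(k) = q^k}
#'
#' Evaluating the Hosoya (Wiener) polynomial at a fixed base `q`. `q = 1` is
#' rejected (constant function, degenerate normalization).
#'
#' @param q positive real base, `q != 1`.
#' @return an `index_function`, non-decreasing iff `q > 1`.
#' @examples
#' geometric_function(2)$fun(3) # 8
#' @export
geometric_function <- function(q) {
  stopifnot(is.numeric(q), length(q) == 1L, is.finite(q), q > 0)
  if (q == 1) {
    stop("q = 1 gives a constant function; normalization would be degenerate",
         call. = FALSE)
  }
  force(q)
  index_function(paste0("geom:", format(q)),
                 function(k) q^k,
                 if (q > 1) "non-decreasing" else "non-increasing",
                 params = list(q = q))
}

#' The built-in catalog of seven index functions
#'
#' The fixed list used for characteristic vectors throughout the clustering
#' experiments, in order:
#' \enumerate{
#'   \item `wiener`: \eqn{f(k) = k}
#'   \item `hyper_wiener`: \eqn{f(k) = (k^2 + k)/2}
#'   \item `power:2`: \eqn{f(k) = k^2}
#'   \item `power:0.5`: \eqn{f(k) = \sqrt k}
#'   \item `harary`: \eqn{f(k) = 1/k}
#'   \item `power:-2`: \eqn{f(k) = 1/k^2}
#'   \item `geom:0.5`: \eqn{f(k) = 2^{-k}}
#' }
#' The first four are non-decreasing, the last three non-increasing. All
#' seven stay numerically bounded for distances up to the ~1000 encountered
#' on large path graphs.
#'
#' @return a named list of 7 `index_function` objects.
#' @examples
#' names(builtin_catalog())
#' @export
builtin_catalog <- function() {
  fns <- list(
    index_function("wiener", function(k) as.numeric(k), "non-decreasing"),
    index_function("hyper_wiener", function(k) (k^2 + k) / 2,
                   "non-decreasing"),
    power_function(2),
    power_function(0.5),
    index_function("harary", function(k) 1 / k, "non-increasing"),
    power_function(-2),
    geometric_function(0.5))
  names(fns) <- vapply(fns, `[[`, "", "name")
  fns
}

#' Look up or parse an index function by name
#'
#' Accepts catalog names (`"wiener"`, `"hyper_wiener"`, `"harary"`) and the
#' parametric forms `"power:ALPHA"` (alias `"generalized:ALPHA"`) and
#' `"geom:Q"`.
#'
#' @param name character specification.
#' @return an `index_function`.
#' @examples
#' lookup_function("generalized:-1")$name
#' @export
lookup_function <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (grepl("^(power|generalized):", name)) {
    return(power_function(as.numeric(sub("^[a-z]+:", "", name))))
  }
  if (grepl("^geom:", name)) {
    return(geometric_function(as.numeric(sub("^geom:", "", name))))
  }
  cat <- builtin_catalog()
  if (!name %in% names(cat)) {
    stop(sprintf("unknown index function '%s'", name), call. = FALSE)
  }
  cat[[name]]
}
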