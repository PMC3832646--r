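## Exhaustive enumeration of small labeled trees and connected graphs, used
## to certify the closed-form extremal values and their uniqueness.

.fw_cache <- new.env(parent = emptyenv())

#' Decode a Prüfer sequence into a labeled tree
#'
#' The Prüfer correspondence is a bijection between sequences of length
#' `n - 2` over `1..n` and labeled trees on `n` nodes, which makes
#' exhaustive tree enumeration a matter of iterating `n^(n-2)` sequences.
#'
#' @param code integer vector of length `n - 2` with entries in `1..n`
#'   (length 0 for `n = 2`).
#' @param n number of nodes.
#' @return 2 x (n - 1) integer matrix of edges.
#' @export
prufer_to_edges <- function(code, n) {
  n <- as.integer(n)
  stopifnot(n >= 2L, length(code) == n - 2L)
  deg <- tabulate(code, n) + 1L
  edges <- matrix(0L, 2L, n - 1L)
  for (i in seq_along(code)) {
    leaf <- which.max(deg == 1L)          # smallest-label leaf
    edges[, i] <- c(leaf, code[i])
    deg[leaf] <- 0L
    deg[code[i]] <- deg[code[i]] - 1L
  }
  edges[, n - 1L] <- which(deg == 1L)
  edges
}

#' Enumerate all labeled trees on n nodes
#'
#' Decodes every Prüfer sequence, yielding exactly `n^(n-2)` trees. Guarded
#' at `n <= 9` (the count grows as `n^(n-2)`).
#'
#' @param n number of nodes, `2 <= n <= 9`.
#' @return list of igraph trees, each connected with `n - 1` edges.
#' @examples
#' length(enumerate_labeled_trees(4)) # 16
#' @export
enumerate_labeled_trees <- function(n) {
  n <- as.integer(n)
  if (n < 2L || n > 9L) stop("`n` must be in 2..9", call. = FALSE)
  codes <- prufer_codes(n)
  lapply(seq_len(nrow(codes)), function(i) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    igraph::add_edges(g, prufer_to_edges(codes[i, ], n))
  })
}

prufer_codes <- function(n) {
  if (n == 2L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L), KEEP.OUT.ATTRS = FALSE))
}

#' Enumerate all connected labeled graphs on n nodes
#'
#' Iterates every edge subset of the complete graph (there are
#' `2^choose(n,2)` of them) and keeps the connected ones. Guarded at
#' `n <= 6`.
#'
#' @param n number of nodes, `2 <= n <= 6`.
#' @return list of connected igraph graphs.
#' @examples
#' length(enumerate_connected_graphs(3)) # 4
#' @export
enumerate_connected_graphs <- function(n) {
  n <- as.integer(n)
  if (n < 2L || n > 6L) stop("`n` must be in 2..6", call. = FALSE)
  scan <- enumeration_scan(n, "graphs")
  lapply(scan$id, function(mask) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    igraph::add_edges(g, mask_to_edges(mask, n))
  })
}

mask_to_edges <- function(mask, n) {
  pairs <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  t(pairs[bitwAnd(mask, bitwShiftL(1L, seq_len(nrow(pairs)) - 1L)) != 0L,
          , drop = FALSE])
}

## One pass over the full enumeration, caching for each graph the distance
## distribution, max degree, sorted degree sequence and an identifier from
## which the graph can be rebuilt (Prüfer row index or edge-subset mask).
enumeration_scan <- function(n, domain) {
  key <- paste0(domain, n)
  hit <- .fw_cache[[key]]
  if (!is.null(hit)) return(hit)

  ut <- upper.tri(matrix(0L, n, n))
  fw_counts <- function(D) {
    for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
    du <- D[ut]
    if (any(!is.finite(du))) return(list(D = D, counts = NULL))
    list(D = D, counts = tabulate(du, nbins = n - 1L))
  }

  if (domain == "trees") {
    codes <- prufer_codes(n)
    nt <- nrow(codes)
    counts <- matrix(0L, nt, n - 1L)
    degs <- matrix(0L, nt, n)
    base <- matrix(Inf, n, n); diag(base) <- 0
    for (i in seq_len(nt)) {
      e <- prufer_to_edges(codes[i, ], n)
      D <- base
      D[cbind(e[1, ], e[2, ])] <- 1
      D[cbind(e[2, ], e[1, ])] <- 1
      r <- fw_counts(D)
      counts[i, ] <- r$counts
      degs[i, ] <- sort(tabulate(e, n))
    }
    res <- list(n = n, domain = domain, id = seq_len(nt), counts = counts,
                degs = degs, maxdeg = degs[, n])
  } else {
    pairs <- which(ut, arr.ind = TRUE)
    m <- nrow(pairs)
    bits <- bitwShiftL(1L, seq_len(m) - 1L)
    base <- matrix(Inf, n, n); diag(base) <- 0
    ids <- integer(0); counts_l <- list(); degs_l <- list()
    for (mask in seq_len(bitwShiftL(1L, m)) - 1L) {
      sel <- bitwAnd(mask, bits) != 0L
      if (sum(sel) < n - 1L) next
      D <- base
      e <- pairs[sel, , drop = FALSE]
      D[e] <- 1
      D[e[, 2:1, drop = FALSE]] <- 1
      r <- fw_counts(D)
      if (is.null(r$counts)) next
      ids <- c(ids, mask)
      counts_l[[length(ids)]] <- r$counts
      degs_l[[length(ids)]] <- sort(rowSums(r$D == 1))
    }
    res <- list(n = n, domain = domain, id = ids,
                counts = do.call(rbind, counts_l),
                degs = do.call(rbind, degs_l))
    res$maxdeg <- res$degs[, n]
  }
  .fw_cache[[key]] <- res
  res
}

rebuild_graph <- function(scan, i) {
  n <- scan$n
  g <- igraph::make_empty_graph(n, directed = FALSE)
  e <- if (scan$domain == "trees") {
    prufer_to_edges(prufer_codes(n)[scan$id[i], ], n)
  } else {
    mask_to_edges(scan$id[i], n)
  }
  igraph::add_edges(g, e)
}

#' Certify the extremal characterizations by exhaustive enumeration
#'
#' Computes `W_f` over every labeled tree (or connected labeled graph) on
#' `n` nodes and checks that the empirical maximum and minimum equal the
#' closed-form extremal values, and that every graph attaining an extreme
#' belongs to the predicted family (path / star / complete, or the broom
#' when a maximum-degree constraint `Delta` is given). Family membership is
#' decided by the sorted degree sequence together with the full distance
#' distribution, which identifies these families uniquely.
#'
#' With `Delta` supplied, the enumeration is restricted to graphs with
#' maximum degree exactly `Delta` and only the maximum (attained by the
#' broom `broom(n, Delta - 1)`) is certified; `min_holds` is `NA`.
#'
#' Uniqueness is only asserted for strictly monotone `f` (on `1..n-1`);
#' constant stretches create legitimate ties that the "if and only if"
#' characterizations exclude.
#'
#' @param n number of nodes (within the enumeration guards; `n >= 4` for
#'   trees, `n >= 3` for graphs when `Delta` is `NULL`).
#' @param f an [index_function()] or name, or a list of them (the
#'   enumeration is scanned once and shared).
#' @param domain `"graphs"` or `"trees"`.
#' @param Delta optional maximum-degree constraint.
#' @return a `verification_report` (or a list of them when `f` is a list):
#'   list with `n`, `domain`, `function_name`, `checked_count`,
#'   `max_holds`, `min_holds`, `extremizer_unique`, `counterexamples`
#'   (list of igraph graphs, empty on success).
#' @examples
#' verify_extremal(5, "wiener", "trees")$max_holds
#' @export
verify_extremal <- function(n, f, domain = c("graphs", "trees"),
                            Delta = NULL) {
  domain <- match.arg(domain)
  n <- as.integer(n)
  single <- !is.list(f) || inherits(f, "index_function")
  fs <- if (single) list(f) else f
  fs <- lapply(fs, as_index_function)
  scan <- enumeration_scan(n, domain)
  reports <- lapply(fs, function(fi) verify_one(scan, fi, Delta))
  if (single) reports[[1]] else reports
}

verify_one <- function(scan, f, Delta) {
  n <- scan$n
  fvals <- f$fun(seq_len(n - 1L))
  strict <- all(diff(fvals) != 0)
  keep <- if (is.null(Delta)) seq_along(scan$id)
          else which(scan$maxdeg == as.integer(Delta))
  w <- as.vector(scan$counts[keep, , drop = FALSE] %*% fvals)
  tol <- function(x) 1e-9 * max(1, abs(x))

  fam_degs <- function(g) sort(igraph::degree(g))
  fam_counts <- function(g) distance_summary(g)$pair_counts
  matches_family <- function(idx, ref_g) {
    rd <- fam_degs(ref_g)
    rc <- c(fam_counts(ref_g), numeric(n - 1L))[seq_len(n - 1L)]
    ok_d <- apply(scan$degs[keep[idx], , drop = FALSE], 1,
                  function(x) all(x == rd))
    ok_c <- apply(scan$counts[keep[idx], , drop = FALSE], 1,
                  function(x) all(abs(x - rc) < 0.5))
    ok_d & ok_c
  }

  counterexamples <- list()
  add_cex <- function(idx) {
    for (i in idx) {
      counterexamples[[length(counterexamples) + 1L]] <<-
        rebuild_graph(scan, keep[i])
    }
  }

  if (!is.null(Delta)) {
    pred <- f_wiener(make_special("broom", n, param = as.integer(Delta) - 1L), f)
    wmax <- max(w)
    max_holds <- abs(wmax - pred) <= tol(pred)
    argmax <- which(w >= wmax - tol(wmax) * 1e-3)
    unique_ok <- NA
    if (strict && f$direction == "non-decreasing") {
      ok <- matches_family(argmax,
                           make_special("broom", n, param = as.integer(Delta) - 1L))
      unique_ok <- all(ok)
      if (!unique_ok) add_cex(argmax[!ok])
    }
    if (!max_holds) add_cex(which.max(w))
    return(structure(list(n = n, domain = scan$domain,
                          function_name = f$name, Delta = as.integer(Delta),
                          checked_count = length(keep),
                          max_holds = max_holds, min_holds = NA,
                          extremizer_unique = unique_ok,
                          counterexamples = counterexamples),
                     class = "verification_report"))
  }

  ex <- extremes(n, f, scan$domain)
  wmax <- max(w); wmin <- min(w)
  max_holds <- abs(wmax - ex$max_value) <= tol(ex$max_value)
  min_holds <- abs(wmin - ex$min_value) <= tol(ex$min_value)
  unique_ok <- NA
  if (strict) {
    ref <- function(fam) make_special(fam, n)
    ok_max <- matches_family(which(w >= wmax - tol(wmax) * 1e-3),
                             ref(ex$maximizer_family))
    ok_min <- matches_family(which(w <= wmin + tol(wmin) * 1e-3),
                             ref(ex$minimizer_family))
    unique_ok <- all(ok_max) && all(ok_min)
    if (!all(ok_max)) add_cex(which(w >= wmax - tol(wmax) * 1e-3)[!ok_max])
    if (!all(ok_min)) add_cex(which(w <= wmin + tol(wmin) * 1e-3)[!ok_min])
  }
  if (!max_holds) add_cex(which.max(w))
  if (!min_holds) add_cex(which.min(w))
  structure(list(n = n, domain = scan$domain, function_name = f$name,
                 Delta = NULL, checked_count = length(keep),
                 max_holds = max_holds, min_holds = min_holds,
                 extremizer_unique = unique_ok,
                 counterexamples = counterexamples),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf(
    "Extremal certification: %s over %s, n = %d%s\n  checked %d graphs; max holds: %s; min holds: %s; extremizers unique: %s; counterexamples: %d\n",
    x$function_name, x$domain, x$n,
    if (!is.null(x$Delta)) sprintf(", max degree %d", x$Delta) else "",
    x$checked_count, x$max_holds, x$min_holds, x$extremizer_unique,
    length(x$counterexamples)))
  invisible(x)
}
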