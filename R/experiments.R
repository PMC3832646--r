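## End-to-end clustering experiments: build a collection of networks or
## trees, compute raw and normalized characteristic vectors, Ward-cluster
## both, cut at the true number of families, and score with the ARI.

#' Build the five-family tree collection
#'
#' For each order in `n_grid`, constructs one tree from each of five
#' families: a path, a star, a broom with `floor(n/2)` pendant leaves, a
#' path-like caterpillar (`t = 2` leaves per spine node) and a star-like
#' caterpillar (`t = 50` leaves per spine node). The broom and caterpillar
#' parameters realize clearly "path-like" and "star-like" shapes at the
#' default orders of several hundred nodes.
#'
#' @param n_grid integer vector of tree orders (each at least 10); default
#'   `seq(500, 950, by = 50)`.
#' @param broom_leaves,cat_path_t,cat_star_t family parameters (see
#'   [make_special()]); `broom_leaves` is a function of `n`.
#' @return list with `graphs` (list of `5 * length(n_grid)` igraph trees,
#'   grouped by family), `truth` (integer family labels) and `families`
#'   (family names).
#' @examples
#' coll <- build_tree_collection(c(20, 30))
#' table(coll$truth)
#' @export
build_tree_collection <- function(n_grid = seq(500L, 950L, by = 50L),
                                  broom_leaves = function(n) n %/% 2L,
                                  cat_path_t = 2L, cat_star_t = 50L) {
  n_grid <- as.integer(n_grid)
  stopifnot(length(n_grid) > 0L, all(n_grid >= 10L))
  builders <- list(
    path = function(n) make_special("path", n),
    star = function(n) make_special("star", n),
    broom = function(n) make_special("broom", n, param = broom_leaves(n)),
    caterpillar_path = function(n) make_special("caterpillar", n,
                                                param = cat_path_t),
    caterpillar_star = function(n) make_special("caterpillar", n,
                                                param = cat_star_t))
  graphs <- list(); truth <- integer(0)
  for (fam in seq_along(builders)) {
    graphs <- c(graphs, lapply(n_grid, builders[[fam]]))
    truth <- c(truth, rep.int(fam, length(n_grid)))
  }
  list(graphs = graphs, truth = truth, families = names(builders))
}

#' Build the three-model random-network collection
#'
#' For each order in `n_grid`, generates one connected network from each of
#' the three random models: Erdős–Rényi G(n, p), preferential attachment
#' with `m` edges per step, and the 3-D geometric model keeping the
#' fraction `q` of closest pairs. Each graph gets its own child seed
#' derived from `seed`, so any single network is reproducible in
#' isolation.
#'
#' @param n_grid integer vector of network orders.
#' @param m preferential-attachment edges per step.
#' @param p Erdős–Rényi edge probability.
#' @param q geometric-model fraction of closest pairs.
#' @param seed integer base seed.
#' @return list with `graphs` (`3 * length(n_grid)` igraph graphs, grouped
#'   by model), `truth` and `families` (`er`, `sf`, `ge`).
#' @export
build_network_collection <- function(n_grid = seq(500L, 950L, by = 50L),
                                     m = 2L, p = 0.05, q = 0.05,
                                     seed = 1L) {
  n_grid <- as.integer(n_grid)
  stopifnot(length(n_grid) > 0L, all(n_grid >= 4L))
  seeds <- matrix(derive_seeds(seed, 3L * length(n_grid)), nrow = 3L)
  graphs <- c(
    lapply(seq_along(n_grid), function(i)
      er_connected(n_grid[i], p, seed = seeds[1L, i])),
    lapply(seq_along(n_grid), function(i)
      preferential_attachment(n_grid[i], m, seed = seeds[2L, i])),
    lapply(seq_along(n_grid), function(i)
      geometric3d(n_grid[i], q, seed = seeds[3L, i])))
  list(graphs = graphs,
       truth = rep(1:3, each = length(n_grid)),
       families = c("er", "sf", "ge"))
}

cluster_and_score <- function(graphs, truth, k, normalized, domain) {
  x <- characteristic_matrix(graphs, normalized = normalized,
                             domain = domain)
  tree <- ward_linkage(x)
  labels <- cut_k(tree, k)
  list(ari = adjusted_rand_index(truth, labels), labels = labels,
       tree = tree, features = x)
}

#' Run one clustering experiment
#'
#' Reproduces the three experiment designs comparing hierarchical
#' clustering on raw versus normalized characteristic vectors:
#' \describe{
#'   \item{exp1.1 .. exp1.5}{collections of random networks, 1 per order in
#'     `n_grid` from each of the ER, preferential-attachment and geometric
#'     models; the sub-experiment number sets the attachment parameter
#'     `m = 1..5`. Clustered into 3 groups; normalization domain
#'     `"graphs"`.}
#'   \item{exp2}{the deterministic five-family tree collection of
#'     [build_tree_collection()], clustered into 5 groups; normalization
#'     domain `"trees"`.}
#'   \item{exp3}{the union of both collections (8 families), clustered into
#'     8 groups; all graphs — including the trees — are normalized on the
#'     `"graphs"` domain so that the whole mixed collection shares one
#'     scale.}
#' }
#' For each replicate the collection is (re)built, both characteristic
#' matrices are computed with the 7-function catalog, each is
#' Ward-clustered and cut at the true number of families, and the two ARIs
#' against the family labels are recorded.
#'
#' @param name one of `"exp1.1"` .. `"exp1.5"`, `"exp2"`, `"exp3"`.
#' @param n_grid orders of the generated graphs; default
#'   `seq(500, 950, by = 50)`.
#' @param reps number of replicates (exp2 is deterministic, so replicates
#'   are collapsed to one).
#' @param seed base seed; each replicate re-seeds the generators with a
#'   derived child seed.
#' @param m,p,q random-model parameters; `m` defaults to the
#'   sub-experiment number for exp1.x and to 2 otherwise.
#' @return an object of class `experiment_result`: list with `name`,
#'   `ari_raw`, `ari_normalized` (per-replicate vectors), `truth`, and the
#'   last replicate's cluster labels (`labels_raw`, `labels_normalized`).
#' @examples
#' \donttest{
#' run_experiment("exp2", n_grid = seq(60, 150, by = 10))
#' }
#' @export
run_experiment <- function(name, n_grid = seq(500L, 950L, by = 50L),
                           reps = 1L, seed = 1L, m = NULL, p = 0.05,
                           q = 0.05) {
  name <- match.arg(name, c(paste0("exp1.", 1:5), "exp2", "exp3"))
  if (is.null(m)) {
    m <- if (startsWith(name, "exp1.")) {
      as.integer(sub("^exp1\\.", "", name))
    } else 2L
  }
  deterministic <- name == "exp2"
  if (deterministic) reps <- 1L
  rep_seeds <- derive_seeds(seed, reps)

  one_rep <- function(r) {
    coll <- switch(substr(name, 1L, 4L),
      exp1 = build_network_collection(n_grid, m = m, p = p, q = q,
                                      seed = rep_seeds[r]),
      exp2 = build_tree_collection(n_grid),
      exp3 = {
        trees <- build_tree_collection(n_grid)
        nets <- build_network_collection(n_grid, m = m, p = p, q = q,
                                         seed = rep_seeds[r])
        list(graphs = c(trees$graphs, nets$graphs),
             truth = c(trees$truth, max(trees$truth) + nets$truth),
             families = c(trees$families, nets$families))
      })
    domain <- if (name == "exp2") "trees" else "graphs"
    k <- length(coll$families)
    raw <- cluster_and_score(coll$graphs, coll$truth, k,
                             normalized = FALSE, domain = domain)
    norm <- cluster_and_score(coll$graphs, coll$truth, k,
                              normalized = TRUE, domain = domain)
    list(raw = raw, norm = norm, truth = coll$truth)
  }

  runs <- lapply(seq_len(reps), one_rep)
  last <- runs[[reps]]
  structure(list(name = name,
                 ari_raw = vapply(runs, function(x) x$raw$ari, numeric(1)),
                 ari_normalized = vapply(runs, function(x) x$norm$ari,
                                         numeric(1)),
                 truth = last$truth,
                 labels_raw = last$raw$labels,
                 labels_normalized = last$norm$labels,
                 n_grid = n_grid, reps = reps, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment %s (%d replicate%s)\n", x$name, x$reps,
              if (x$reps > 1) "s" else ""))
  cat(sprintf("  ARI raw:        %s\n", fmt_mean_sd(x$ari_raw)))
  cat(sprintf("  ARI normalized: %s\n", fmt_mean_sd(x$ari_normalized)))
  invisible(x)
}

fmt_mean_sd <- function(x) {
  if (length(x) == 1L) sprintf("%.2f", x)
  else sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
}

#' Summarize experiment results as a table
#'
#' One row per experiment with the mean ARI (and, for replicated runs, the
#' standard deviation in parentheses) for the raw and normalized feature
#' vectors.
#'
#' @param results a single `experiment_result` or a list of them.
#' @param file optional path; when given the table is also written as CSV.
#' @return data.frame with columns `experiment`, `raw`, `normalized`.
#' @export
summarize_experiments <- function(results, file = NULL) {
  if (inherits(results, "experiment_result")) results <- list(results)
  if (length(results) == 0L) stop("no results to summarize", call. = FALSE)
  out <- data.frame(
    experiment = vapply(results, `[[`, "", "name"),
    raw = vapply(results, function(x) fmt_mean_sd(x$ari_raw), ""),
    normalized = vapply(results, function(x) fmt_mean_sd(x$ari_normalized),
                        ""),
    stringsAsFactors = FALSE)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
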