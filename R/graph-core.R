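#' fwiener: functional Wiener indices and size-normalized network descriptors
#'
#' Distance-based topological descriptors of the form
#' \eqn{W_f(G) = \sum_{\{u,v\}} f(d(u,v))} for a monotone function \eqn{f},
#' their sharp extremal values over connected graphs and trees, the
#' normalized index \eqn{N_f \in [0,1]}, random-network generators, and
#' Ward clustering of network collections on characteristic index vectors.
#'
#' Graphs are plain \pkg{igraph} objects: every function in the package
#' accepts an undirected simple \code{igraph} graph and validates it.
#'
#' @keywords internal
#' @importFrom stats hclust cutree dist runif sd
#' @importFrom utils head
"_PACKAGE"

## ---- validation -----------------------------------------------------------

#' Validate a graph argument
#'
#' Checks that `g` is an undirected simple igraph graph (no self-loops, no
#' multiple edges). Used internally by every graph-consuming function.
#'
#' @param g object to validate.
#' @param arg name used in error messages.
#' @return `g`, invisibly.
#' @keywords internal
assert_graph <- function(g, arg = "g") {
  if (!igraph::is_igraph(g)) {
    stop(sprintf("`%s` must be an igraph graph", arg), call. = FALSE)
  }
  if (igraph::is_directed(g)) {
    stop(sprintf("`%s` must be undirected", arg), call. = FALSE)
  }
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    stop(sprintf("`%s` must be simple (no self-loops or multi-edges)", arg),
         call. = FALSE)
  }
  invisible(g)
}

#' Is the graph connected?
#'
#' Thin wrapper over [igraph::is_connected()] restricted to the undirected
#' simple graphs this package works with.
#'
#' @param g an undirected simple igraph graph.
#' @return `TRUE` if every pair of nodes is joined by a path.
#' @examples
#' is_connected(make_special("path", 5))
#' @export
is_connected <- function(g) {
  assert_graph(g)
  igraph::vcount(g) <= 1L || igraph::is_connected(g)
}

#' Maximum degree of a graph
#'
#' @param g an undirected simple igraph graph.
#' @return the largest node degree \eqn{\Delta(G)}; 0 for an edgeless graph.
#' @examples
#' max_degree(make_special("star", 7)) # 6
#' @export
max_degree <- function(g) {
  assert_graph(g)
  if (igraph::vcount(g) == 0L) return(0L)
  as.integer(max(igraph::degree(g)))
}

is_tree_graph <- function(g) {
  igraph::ecount(g) == igraph::vcount(g) - 1L && is_connected(g)
}

## ---- special families -----------------------------------------------------

#' Construct a special graph family member
#'
#' Builds the named graphs used as extremal references: paths, stars,
#' complete graphs, caterpillars, brooms and kites.
#'
#' Constructions (nodes are `1..n`):
#' \describe{
#'   \item{path}{nodes chained `1-2-...-n`.}
#'   \item{star}{node 1 adjacent to all others.}
#'   \item{complete}{every pair adjacent.}
#'   \item{broom}{`param = l` pendant leaves: a path spine on `n - l` nodes
#'     with `l` extra leaves attached to one terminal spine node, which then
#'     has degree `l + 1`. `broom(n, 1)` is the path, `broom(n, n - 2)` the
#'     star.}
#'   \item{caterpillar}{`param = t` leaves per spine node: a spine path of
#'     `ceiling(n / (t + 1))` nodes, each carrying `t` pendant leaves except
#'     the last spine node, which carries the remainder.}
#'   \item{kite}{`param = c` clique size: a complete graph on `c` nodes and a
#'     path on `n - c` nodes joined by a single bridge edge.}
#' }
#'
#' Degenerate orders are defined naturally: `path(1)`, `star(1)`,
#' `complete(1)` are the single node; `star(2)` and `complete(2)` are the
#' single edge.
#'
#' @param family one of `"path"`, `"star"`, `"complete"`, `"caterpillar"`,
#'   `"broom"`, `"kite"`.
#' @param n number of nodes (positive integer).
#' @param param family parameter: leaves-per-spine-node `t >= 1`
#'   (caterpillar), pendant-leaf count `1 <= l <= n - 2` (broom), or clique
#'   size `3 <= c <= n - 1` (kite). Ignored for the other families.
#' @return an undirected simple igraph graph on `n` nodes with graph
#'   attribute `family`.
#' @examples
#' make_special("path", 4)
#' make_special("broom", 6, param = 2)
#' @export
make_special <- function(family, n, param = NULL) {
  family <- match.arg(family,
                      c("path", "star", "complete", "caterpillar", "broom",
                        "kite"))
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  edges <- switch(family,
    path = {
      if (n == 1L) integer(0) else rbind(1:(n - 1L), 2:n)
    },
    star = {
      if (n == 1L) integer(0) else rbind(1L, 2:n)
    },
    complete = {
      if (n == 1L) integer(0) else utils::combn(n, 2L)
    },
    broom = {
      l <- as.integer(param)
      if (length(l) != 1L || is.na(l) || l < 1L || l > n - 2L) {
        stop("broom requires pendant-leaf count `param` with 1 <= param <= n - 2",
             call. = FALSE)
      }
      s <- n - l                      # spine length, >= 2
      spine <- if (s > 1L) rbind(1:(s - 1L), 2:s) else NULL
      leaves <- rbind(s, (s + 1L):n)  # leaves hang off the last spine node
      cbind(spine, leaves)
    },
    caterpillar = {
      t <- as.integer(param)
      if (length(t) != 1L || is.na(t) || t < 1L) {
        stop("caterpillar requires leaves-per-spine-node `param` >= 1",
             call. = FALSE)
      }
      s <- ceiling(n / (t + 1L))
      spine <- if (s > 1L) rbind(1:(s - 1L), 2:s) else NULL
      # full allotment of t leaves on spine nodes 1..s-1, remainder on node s
      leaf_owner <- rep.int(seq_len(s), times = c(rep.int(t, s - 1L),
                                                  n - s - (s - 1L) * t))
      leaves <- if (n > s) rbind(leaf_owner, (s + 1L):n) else NULL
      cbind(spine, leaves)
    },
    kite = {
      c_ <- as.integer(param)
      if (length(c_) != 1L || is.na(c_) || c_ < 3L || c_ > n - 1L) {
        stop("kite requires clique size `param` with 3 <= param <= n - 1",
             call. = FALSE)
      }
      clique <- utils::combn(c_, 2L)
      tail_n <- n - c_
      tail <- if (tail_n > 1L) rbind((c_ + 1L):(n - 1L), (c_ + 2L):n) else NULL
      bridge <- rbind(c_, c_ + 1L)    # clique node c_ to one end of the path
      cbind(clique, tail, bridge)
    })
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges) > 0L) g <- igraph::add_edges(g, as.vector(edges))
  igraph::graph_attr(g, "family") <- family
  g
}

## ---- distance summary -----------------------------------------------------

#' Distance distribution of a connected graph
#'
#' Runs breadth-first search from every node and tabulates `pair_counts[k]`,
#' the number of unordered node pairs at shortest-path distance exactly `k`,
#' for `k = 1..diameter`. This vector is a sufficient statistic for every
#' f-Wiener index: \eqn{W_f(G) = \sum_k D_k f(k)}.
#'
#' @param g a connected undirected simple igraph graph.
#' @return an object of class `distance_summary`: a list with
#'   `pair_counts` (named numeric vector, names `"1".."diameter"`) and
#'   `node_count`.
#' @examples
#' distance_summary(make_special("path", 4)) # counts 3, 2, 1
#' @export
distance_summary <- function(g) {
  assert_graph(g)
  n <- igraph::vcount(g)
  if (n < 1L) stop("graph has no nodes", call. = FALSE)
  if (!is_connected(g)) {
    stop("graph is disconnected: pairwise distances are undefined",
         call. = FALSE)
  }
  if (n == 1L) {
    counts <- numeric(0)
  } else {
    d <- igraph::distances(g, algorithm = "unweighted")
    du <- d[upper.tri(d)]
    counts <- tabulate(du, nbins = max(du))
  }
  counts <- as.numeric(counts)
  names(counts) <- as.character(seq_along(counts))
  structure(list(pair_counts = counts, node_count = n),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("Distance summary of a connected graph on %d nodes\n",
              x$node_count))
  if (length(x$pair_counts)) {
    tab <- rbind(distance = seq_along(x$pair_counts),
                 pairs = unname(x$pair_counts))
    dimnames(tab)[[2]] <- rep("", ncol(tab))
    print(tab)
  }
  invisible(x)
}

## ---- file I/O -------------------------------------------------------------

#' Read a graph from a whitespace-separated edge list
#'
#' Each non-comment line holds two node labels separated by tabs or spaces.
#' Lines starting with `#` and blank lines are ignored. Labels are arbitrary
#' strings, mapped to node indices in order of first appearance and kept as
#' the vertex `name` attribute. Self-loops and duplicate edges (in either
#' orientation) are rejected.
#'
#' @param path path to the edge-list file.
#' @return an undirected simple igraph graph with vertex names.
#' @seealso [write_edge_list()], [read_graphml()]
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  labels <- character(0)
  ei <- integer(0); ej <- integer(0)
  seen <- new.env(parent = emptyenv())
  for (ln in which(keep)) {
    tok <- strsplit(trimws(lines[[ln]]), "\\s+")[[1]]
    if (length(tok) != 2L) {
      stop(sprintf("line %d: expected two node labels, got %d token(s)",
                   ln, length(tok)), call. = FALSE)
    }
    if (tok[1] == tok[2]) {
      stop(sprintf("line %d: self-loop on node '%s' not allowed", ln, tok[1]),
           call. = FALSE)
    }
    idx <- match(tok, labels)
    if (anyNA(idx)) {
      new <- tok[is.na(idx)]
      labels <- c(labels, unique(new))
      idx <- match(tok, labels)
    }
    key <- paste(sort(idx), collapse = "-")
    if (!is.null(seen[[key]])) {
      stop(sprintf("line %d: duplicate edge %s-%s", ln, tok[1], tok[2]),
           call. = FALSE)
    }
    seen[[key]] <- TRUE
    ei <- c(ei, idx[1]); ej <- c(ej, idx[2])
  }
  g <- igraph::make_empty_graph(length(labels), directed = FALSE)
  if (length(ei)) g <- igraph::add_edges(g, rbind(ei, ej))
  if (length(labels)) igraph::V(g)$name <- labels
  g
}

#' Write a graph as a tab-separated edge list
#'
#' @param g an undirected simple igraph graph; vertex names are used when
#'   present, otherwise 1-based indices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  assert_graph(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  invisible(path)
}

#' Read / write GraphML
#'
#' GraphML import and export for interoperability with other network tools.
#' On import the graph is coerced to a simple undirected graph; edge and
#' graph attributes other than vertex names are ignored.
#'
#' @param path file path.
#' @return `read_graphml()` returns an igraph graph; `write_graphml()`
#'   returns `path` invisibly.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g)
  g
}

#' @param g an undirected simple igraph graph.
#' @rdname read_graphml
#' @export
write_graphml <- function(g, path) {
  assert_graph(g)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
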