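test_that("special-family constructors produce the expected graphs", {
  p4 <- make_special("path", 4)
  expect_equal(igraph::vcount(p4), 4)
  expect_equal(igraph::ecount(p4), 3)
  expect_equal(sort(igraph::degree(p4)), c(1, 1, 2, 2))
  expect_equal(igraph::diameter(p4), 3)

  s5 <- make_special("star", 5)
  expect_equal(sort(igraph::degree(s5), decreasing = TRUE), c(4, 1, 1, 1, 1))
  expect_equal(igraph::diameter(s5), 2)

  k6 <- make_special("complete", 6)
  expect_equal(igraph::ecount(k6), choose(6, 2))

  b5 <- make_special("broom", 5, param = 2)
  expect_equal(sort(igraph::degree(b5), decreasing = TRUE), c(3, 2, 1, 1, 1))

  # kite(n, c): clique edges + path edges + one bridge
  kite <- make_special("kite", 6, param = 4)
  expect_equal(igraph::ecount(kite), choose(4, 2) + 1 + 1)
  expect_equal(max_degree(kite), 4)

  # every family is connected with the closed-form edge count
  cases <- list(list("path", 9, NULL, 8), list("star", 9, NULL, 8),
                list("complete", 7, NULL, 21), list("broom", 12, 5, 11),
                list("caterpillar", 17, 3, 16),
                list("kite", 9, 5, choose(5, 2) + 3 + 1))
  for (cs in cases) {
    g <- make_special(cs[[1]], cs[[2]], param = cs[[3]])
    expect_true(is_connected(g))
    expect_equal(igraph::vcount(g), cs[[2]])
    expect_equal(igraph::ecount(g), cs[[4]])
  }
})

test_that("caterpillar spine and leaf allocation follow the construction rule", {
  # n = 500, t = 50: 10 spine nodes, 9 full, the last carries the remainder
  g <- make_special("caterpillar", 500, param = 50)
  expect_true(is_tree_ish <- igraph::ecount(g) == 499 && is_connected(g))
  deg <- igraph::degree(g)
  expect_equal(sum(deg > 1), 10)          # spine size ceiling(500/51)
  # a caterpillar with t >= n - 1 collapses to a star
  expect_equal(sort(igraph::degree(make_special("caterpillar", 20, 50))),
               sort(igraph::degree(make_special("star", 20))))
})

test_that("constructors validate their parameters", {
  expect_error(make_special("broom", 5, param = 4), "1 <= param <= n - 2")
  expect_error(make_special("kite", 6, param = 2), "3 <= param")
  expect_error(make_special("kite", 6, param = 6), "param <= n - 1")
  expect_error(make_special("caterpillar", 6, param = 0), ">= 1")
  expect_error(make_special("pentagon", 5), "'arg' should be one of")
  expect_error(make_special("path", 0), "positive integer")
  # degenerate orders are defined
  expect_equal(igraph::vcount(make_special("path", 1)), 1)
  expect_equal(igraph::ecount(make_special("star", 2)), 1)
  expect_equal(igraph::ecount(make_special("complete", 1)), 0)
})

test_that("distance_summary matches hand counts and sums to choose(n,2)", {
  expect_equal(distance_summary(make_special("path", 4))$pair_counts,
               c("1" = 3, "2" = 2, "3" = 1))
  expect_equal(distance_summary(make_special("complete", 5))$pair_counts,
               c("1" = 10))
  expect_equal(distance_summary(make_special("star", 5))$pair_counts,
               c("1" = 4, "2" = 6))
  for (seed in 1:20) {
    n <- 5 + (seed %% 20)
    g <- rand_connected(n, seed = seed)
    ds <- distance_summary(g)
    expect_equal(sum(ds$pair_counts), choose(n, 2))
    expect_true(all(ds$pair_counts[-length(ds$pair_counts)] >= 0))
  }
})

test_that("distance_summary agrees with a Floyd-Warshall oracle", {
  withr::with_seed(42, {
    for (i in 1:25) {
      n <- sample(4:30, 1)
      g <- rand_connected(n)
      D <- fw_dist_oracle(g)
      du <- D[upper.tri(D)]
      expect_equal(unname(distance_summary(g)$pair_counts),
                   as.numeric(tabulate(du, nbins = max(du))))
    }
  })
})

test_that("distance_summary is invariant under node relabeling", {
  withr::with_seed(7, {
    for (i in 1:10) {
      g <- rand_connected(sample(5:25, 1))
      perm <- sample(igraph::vcount(g))
      gp <- igraph::permute(g, perm)
      expect_equal(distance_summary(g)$pair_counts,
                   distance_summary(gp)$pair_counts)
    }
  })
})

test_that("distance_summary refuses disconnected graphs", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  g <- igraph::add_edges(g, c(1, 2, 3, 4))
  expect_false(is_connected(g))
  expect_error(distance_summary(g), "disconnected")
})

test_that("is_connected and max_degree report basic invariants", {
  expect_equal(max_degree(make_special("star", 7)), 6)
  expect_equal(max_degree(make_special("path", 9)), 2)
  expect_true(is_connected(make_special("path", 1)))
  expect_error(max_degree("not a graph"), "igraph")
})

test_that("edge-list files round-trip and reject malformed input", {
  f <- withr::local_tempfile()
  writeLines(c("# a comment", "a\tb", "b c", ""), f)
  g <- read_edge_list(f)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::V(g)$name, c("a", "b", "c"))  # first-appearance order
  expect_equal(unname(sort(igraph::degree(g))), c(1, 1, 2))  # it is P3

  writeLines("a\ta", f)
  expect_error(read_edge_list(f), "line 1: self-loop")
  writeLines(c("a b", "b\ta"), f)
  expect_error(read_edge_list(f), "line 2: duplicate")
  writeLines(c("a b", "x y z"), f)
  expect_error(read_edge_list(f), "line 2: expected two")

  k3 <- make_special("complete", 3)
  write_edge_list(k3, f)
  back <- read_edge_list(f)
  expect_equal(igraph::vcount(back), 3)
  expect_equal(igraph::ecount(back), 3)

  # round trip preserves the distance structure of a larger random graph
  g0 <- rand_connected(15, seed = 11)
  write_edge_list(g0, f)
  g1 <- read_edge_list(f)
  expect_equal(distance_summary(g1)$pair_counts,
               distance_summary(g0)$pair_counts)
})

test_that("GraphML round-trips through the standard format", {
  f <- withr::local_tempfile(fileext = ".graphml")
  g0 <- make_special("broom", 8, param = 3)
  write_graphml(g0, f)
  g1 <- read_graphml(f)
  expect_equal(igraph::vcount(g1), 8)
  expect_equal(sort(igraph::degree(g1)), sort(igraph::degree(g0)))
  expect_equal(distance_summary(g1)$pair_counts,
               distance_summary(g0)$pair_counts)
})
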