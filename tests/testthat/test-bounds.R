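test_that("closed-form family values equal the constructed-graph indices", {
  for (n in c(2, 3, 5, 12, 40)) {
    for (f in builtin_catalog()) {
      expect_equal(path_value(n, f),
                   if (n >= 2) f_wiener(make_special("path", n), f),
                   info = sprintf("path n=%d f=%s", n, f$name))
      expect_equal(star_value(n, f),
                   f_wiener(make_special("star", n), f))
      expect_equal(complete_value(n, f),
                   f_wiener(make_special("complete", n), f))
    }
  }
  expect_equal(path_value(5, "wiener"), 20)
  expect_equal(star_value(5, "wiener"), 16)
  expect_equal(complete_value(5, "wiener"), 10)
  expect_error(path_value(1, "wiener"), ">= 2")
})

test_that("extremes orient min and max by the direction of f", {
  ex <- extremes(5, "wiener", "graphs")
  expect_equal(ex$min_value, 10); expect_equal(ex$minimizer_family, "complete")
  expect_equal(ex$max_value, 20); expect_equal(ex$maximizer_family, "path")

  ext <- extremes(5, "wiener", "trees")
  expect_equal(ext$min_value, 16); expect_equal(ext$minimizer_family, "star")
  expect_equal(ext$max_value, 20)

  # non-increasing f: path becomes the minimizer
  exh <- extremes(4, "harary", "graphs")
  expect_equal(exh$min_value, 3 + 2 / 2 + 1 / 3)  # path: D = {1:3, 2:2, 3:1}
  expect_equal(exh$minimizer_family, "path")
  expect_equal(exh$max_value, 6)                  # complete graph
  expect_error(extremes(2, "wiener", "graphs"), ">= 3")
  expect_error(extremes(3, "wiener", "trees"), ">= 4")
})

test_that("swapping f for -f exchanges and negates the extremes", {
  neg_harary <- index_function("neg_harary", function(k) -1 / k,
                               "non-decreasing")
  for (n in c(5, 9, 14)) {
    for (domain in c("graphs", "trees")) {
      a <- extremes(n, "harary", domain)
      b <- extremes(n, neg_harary, domain)
      expect_equal(a$min_value, -b$max_value)
      expect_equal(a$max_value, -b$min_value)
      expect_equal(a$minimizer_family, b$maximizer_family)
      expect_equal(a$maximizer_family, b$minimizer_family)
    }
  }
})

test_that("every f-Wiener value is sandwiched by the sharp bounds", {
  cat7 <- builtin_catalog()
  withr::with_seed(31, {
    for (i in 1:60) {
      n <- sample(5:40, 1)
      g <- rand_connected(n)
      for (f in cat7) {
        ex <- extremes(n, f, "graphs")
        w <- f_wiener(g, f)
        expect_gte(w, ex$min_value - 1e-9)
        expect_lte(w, ex$max_value + 1e-9)
      }
    }
    # same over random labeled trees, against the trees domain
    for (i in 1:60) {
      n <- sample(5:40, 1)
      g <- rand_tree(n)
      for (f in cat7) {
        ex <- extremes(n, f, "trees")
        w <- f_wiener(g, f)
        expect_gte(w, ex$min_value - 1e-9)
        expect_lte(w, ex$max_value + 1e-9)
      }
    }
  })
})

test_that("normalization maps path to 0 and the dense family to 1", {
  expect_equal(normalized_index(make_special("path", 5), "wiener", "trees"), 0)
  expect_equal(normalized_index(make_special("star", 5), "wiener", "trees"), 1)
  expect_equal(normalized_index(make_special("star", 5), "wiener", "graphs"),
               0.4)
  expect_equal(normalized_index(make_special("complete", 7), "wiener",
                                "graphs"), 1)
  # path |-> 0 and dense |-> 1 for every catalog f, both domains
  for (f in builtin_catalog()) {
    expect_equal(normalized_index(make_special("path", 12), f, "graphs"), 0)
    expect_equal(normalized_index(make_special("complete", 12), f, "graphs"), 1)
    expect_equal(normalized_index(make_special("path", 12), f, "trees"), 0)
    expect_equal(normalized_index(make_special("star", 12), f, "trees"), 1)
  }
})

test_that("graph-normalized Wiener index of the star equals (n-3)/n", {
  for (n in 4:50) {
    expect_equal(normalized_index(make_special("star", n), "wiener", "graphs"),
                 (n - 3) / n, tolerance = 1e-12)
  }
})

test_that("normalization validates its domain and rejects non-trees", {
  expect_error(normalized_index(make_special("complete", 5), "wiener",
                                "trees"), "not a tree")
  expect_error(normalized_index(make_special("path", 3), "wiener", "trees"),
               ">= 4")
  # values stay within [0,1] for arbitrary connected graphs
  withr::with_seed(17, {
    for (i in 1:25) {
      g <- rand_connected(sample(5:30, 1))
      for (f in builtin_catalog()) {
        v <- normalized_index(g, f, "graphs")
        expect_gte(v, 0); expect_lte(v, 1)
      }
    }
  })
})

test_that("exhaustively, N_f = 0 only for paths and 1 only for the dense family", {
  wiener <- lookup_function("wiener")
  for (g in enumerate_connected_graphs(5)) {
    v <- normalized_index(g, wiener, "graphs")
    deg <- igraph::degree(g)
    if (v == 0) expect_true(all(deg <= 2) && igraph::ecount(g) == 4)
    if (v == 1) expect_equal(igraph::ecount(g), choose(5, 2))
  }
  for (g in enumerate_labeled_trees(6)) {
    v <- normalized_index(g, wiener, "trees")
    if (v == 0) expect_true(all(igraph::degree(g) <= 2))
    if (v == 1) expect_equal(max_degree(g), 5)
  }
})

test_that("degree-constrained maximum is the broom, matching enumeration", {
  # boundary cases collapse to path and star
  expect_equal(degree_constrained_max(9, 2, "wiener")$value,
               path_value(9, "wiener"))
  expect_equal(degree_constrained_max(5, 4, "wiener")$value, 16)
  # brute-force maximum over all labeled trees on 6 nodes with max degree 3
  w6 <- vapply(enumerate_labeled_trees(6), function(g) {
    if (max_degree(g) == 3) f_wiener(g, "wiener") else -Inf
  }, numeric(1))
  expect_equal(degree_constrained_max(6, 3, "wiener")$value, max(w6))
  expect_equal(max_degree(degree_constrained_max(6, 3, "wiener")$extremal_graph),
               3)
  expect_error(degree_constrained_max(6, 6, "wiener"), "Delta")
  expect_error(degree_constrained_max(6, 3, "harary"), "non-decreasing")
})

test_that("corollary bounds equal the general extremes and their closed forms", {
  ex <- corollary_bounds(5, "wiener", "graphs")
  expect_equal(c(ex$min_value, ex$max_value), c(10, 20))
  for (n in 3:60) {
    exw <- corollary_bounds(n, "wiener", "graphs")
    expect_equal(exw$min_value, n * (n - 1) / 2)
    expect_equal(exw$max_value, n * (n + 1) * (n - 1) / 6)
    exh <- corollary_bounds(n, "hyper_wiener", "graphs")
    expect_equal(exh$max_value, path_value(n, "hyper_wiener"))
    if (n >= 4) {
      ext <- corollary_bounds(n, "wiener", "trees")
      expect_equal(ext$min_value, (n - 1)^2)  # star value for f(k) = k
    }
  }
})

test_that("the star-proximity threshold is monotone machinery that finds 26", {
  # on a short range the required excess is already near the asymptotic one
  c_small <- star_proximity_threshold(10:60)
  expect_true(c_small >= 20 && c_small <= 26)
  per_n <- attr(c_small, "per_n")
  expect_true(all(per_n$m > per_n$n & per_n$m <= 2 * per_n$n))
})
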