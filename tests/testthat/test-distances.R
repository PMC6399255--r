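test_that("toy age/sex distance reproduces the worked example's distances", {
  attrs <- toy_network_attrs()
  g <- pr_graph(5, attrs = attrs, directed = TRUE)
  spec <- distance_spec("toy_age_sex")
  # Alice (30, F) against Bob, Cecil, Diane, Eve
  expect_equal(evaluate_distance(spec, g, 1, 2:5), c(20, 15, 10, 5))
  # Bob (40, M): Cecil and Eve tie at 15
  expect_equal(evaluate_distance(spec, g, 2, c(1, 3, 4, 5)), c(20, 15, 30, 15))
})

test_that("toy rankings print the published selection probabilities", {
  rk <- toy_rankings()
  expect_equal(rk$Alice$prob, c(12, 6, 4, 3) / 25)
  expect_equal(rk$Alice$percent, c(48, 24, 16, 12))
  expect_equal(rk$Bob$rank, c(1, 1, 3, 4))
  expect_equal(rk$Bob$prob, c(12, 12, 4, 3) / 31)
  expect_equal(rk$Cecil$prob, c(4, 4, 4, 1) / 13)
  expect_equal(rk$Diane$prob, c(4, 2, 2, 1) / 9)
})

test_that("cosine distance hits its definition limits and closed form", {
  attrs <- data.frame(x = c(1, 2, 0, 1), y = c(0, 0, 1, 1))
  g <- pr_graph(4, attrs = attrs, directed = TRUE)
  spec <- distance_spec("cosine", bindings = c("x", "y"))
  d <- evaluate_distance(spec, g, 1, 2:4)
  expect_lt(d[1], 1e-5)                       # parallel vectors
  expect_equal(d[2], 1, tolerance = 1e-5)     # orthogonal
  expect_equal(d[3], 1 - sqrt(2) / 2, tolerance = 1e-5)
})

test_that("centrality distances smooth zero centrality by 1/eps", {
  g <- pr_graph(4, directed = TRUE)  # no edges: all degrees zero
  spec <- distance_spec("degree", mode = "dynamic", eps = 1e-6)
  expect_equal(evaluate_distance(spec, g, 1, 2:4), rep(1e6, 3))
})

test_that("disassortative distance follows the degree-ratio formula", {
  # vertex 1 has degree 6; vertices 2 and 3 have degree 2
  el <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(1, 6), c(1, 7), c(2, 3))
  g <- pr_graph(7, directed = FALSE, edges = el)
  expect_equal(disassortative_distance(g, 1, 2), 6 - 6 / 2)      # = 3
  expect_equal(disassortative_distance(g, 2, 3), 6 - 1)          # deg* - 1
  # ranking from a degree-6 source over candidates of degree 1, 2, 6:
  # the lowest-degree candidate is nearest
  d <- disassortative_distance(g, 1, c(4, 2, 1))
  expect_equal(order(d), c(1, 2, 3))
})

test_that("hierarchical distance mixes euclidean and class-rank parts", {
  attrs <- data.frame(x = c(0, 2, 0), cls = c(1L, 5L, 1L))
  g <- pr_graph(3, attrs = attrs, directed = TRUE)
  pure_e <- distance_spec("hierarchical", bindings = "x",
                          class_column = "cls", alpha = 1)
  expect_equal(evaluate_distance(pure_e, g, 1, 2), 2)
  mix <- distance_spec("hierarchical", bindings = "x",
                       class_column = "cls", alpha = 0.5)
  expect_equal(evaluate_distance(mix, g, 1, 2), 0.5 * 2 + 0.5 * 4)
  # alpha = 0, identical class and position: positivity kept by jitter
  pure_h <- distance_spec("hierarchical", bindings = "x",
                          class_column = "cls", alpha = 0)
  d <- evaluate_distance(pure_h, g, 1, 3)
  expect_gt(d, 0)
  expect_lt(d, 1e-9)
  attrs_bad <- data.frame(x = 1:3, cls = factor(c("a", "b", "c")))
  g_bad <- pr_graph(3, attrs = attrs_bad, directed = TRUE)
  expect_error(
    evaluate_distance(distance_spec("hierarchical", bindings = "x",
                                    class_column = "cls"), g_bad, 1, 2),
    "ordered")
})

test_that("every family returns finite nonnegative distances on random tables", {
  set.seed(31)
  attrs <- fixture_attrs(12)
  g <- priority_rank_generate(12, 2, distance_spec("random"), attrs = attrs)
  specs <- list(
    distance_spec("random"),
    distance_spec("degree", mode = "dynamic"),
    distance_spec("betweenness", mode = "dynamic"),
    distance_spec("closeness", mode = "dynamic"),
    distance_spec("pagerank", mode = "dynamic"),
    distance_spec("euclidean1d", bindings = "x"),
    distance_spec("euclidean2d", bindings = c("x", "y")),
    distance_spec("cosine", bindings = c("x", "y")),
    distance_spec("aggregate", bindings = c("x", "grade", "group")),
    distance_spec("hierarchical", bindings = "x", class_column = "grade"),
    distance_spec("disassortative")
  )
  for (spec in specs) {
    for (src in c(1, 5, 12)) {
      d <- evaluate_distance(spec, g, src, setdiff(1:12, src))
      expect_length(d, 11)
      expect_true(all(is.finite(d)))
      expect_true(all(d >= 0))
    }
  }
  expect_error(
    evaluate_distance(distance_spec("euclidean1d", bindings = "nope"), g, 1, 2),
    "not found")
})

test_that("symmetric families are symmetric; euclidean obeys the triangle inequality", {
  attrs <- fixture_attrs(10, seed = 99)
  g <- pr_graph(10, attrs = attrs, directed = TRUE)
  for (spec in list(distance_spec("euclidean1d", bindings = "x"),
                    distance_spec("euclidean2d", bindings = c("x", "y")),
                    distance_spec("cosine", bindings = c("x", "y")))) {
    for (pair in list(c(1, 2), c(3, 7), c(4, 10))) {
      expect_equal(evaluate_distance(spec, g, pair[1], pair[2]),
                   evaluate_distance(spec, g, pair[2], pair[1]),
                   tolerance = 1e-12)
    }
  }
  e2 <- distance_spec("euclidean2d", bindings = c("x", "y"))
  for (trip in list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))) {
    dij <- evaluate_distance(e2, g, trip[1], trip[2])
    djk <- evaluate_distance(e2, g, trip[2], trip[3])
    dik <- evaluate_distance(e2, g, trip[1], trip[3])
    expect_lte(dik, dij + djk + 1e-12)
  }
})

test_that("dynamic degree distance makes selection favor high-degree candidates", {
  el <- rbind(c(2, 3), c(2, 4), c(2, 5), c(3, 4))  # deg: v2=3, v3=2, v4=2, v5=1
  g <- pr_graph(6, directed = FALSE, edges = el)
  spec <- distance_spec("degree", mode = "dynamic")
  d <- evaluate_distance(spec, g, 1, c(2, 3, 5, 6))
  expect_true(all(diff(d) > 0))  # distance increases as degree decreases
  pmf <- selection_pmf(competition_positions(d))
  expect_true(all(diff(pmf$probabilities) <= 0))
})
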