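test_that("degenerate sizes: two vertices link reciprocally, k = n-1 is complete", {
  g2 <- priority_rank_generate(2, 1, distance_spec("random"), seed = 1)
  el <- igraph::as_edgelist(g2)
  expect_equal(nrow(el), 2)
  expect_setequal(paste(el[, 1], el[, 2]), c("1 2", "2 1"))

  g5 <- priority_rank_generate(5, 4, distance_spec("random"), seed = 2)
  expect_equal(igraph::ecount(g5), 20)
  expect_equal(sum(igraph::which_loop(g5)), 0)
})

test_that("configured out-degrees are honored exactly, for constant and per-vertex rules", {
  g <- priority_rank_generate(20, 3, distance_spec("random"), seed = 3)
  expect_true(all(igraph::degree(g, mode = "out") == 3))
  kvec <- rep(c(1L, 2L, 4L, 5L), 5)
  gk <- priority_rank_generate(20, kvec, distance_spec("random"), seed = 4)
  expect_equal(igraph::degree(gk, mode = "out"), kvec,
               ignore_attr = TRUE)
  expect_error(priority_rank_generate(5, 5, distance_spec("random")),
               "exceeds")
})

test_that("generated graphs are always simple", {
  for (s in 1:5) {
    g <- priority_rank_generate(15, 4, distance_spec("degree", mode = "dynamic"),
                                seed = s, p_rw = 0.2)
    expect_equal(sum(igraph::which_loop(g)), 0)
    expect_false(igraph::any_multiple(g))
  }
})

test_that("simplification merges reciprocal edges, shrinks, and is idempotent", {
  g <- pr_graph(3, directed = TRUE, edges = rbind(c(1, 2), c(2, 1), c(2, 3)))
  gs <- simplify_network(g)
  expect_false(igraph::is_directed(gs))
  expect_equal(igraph::ecount(gs), 2)
  expect_lte(igraph::ecount(gs), igraph::ecount(g))
  expect_equal(igraph::ecount(simplify_network(gs)), igraph::ecount(gs))
})

test_that("random distance gives uniform edge probability over ordered pairs", {
  set.seed(12)
  n <- 5
  counts <- matrix(0, n, n)
  for (rep in 1:3000) {
    el <- igraph::as_edgelist(
      priority_rank_generate(n, 1, distance_spec("random")), names = FALSE)
    counts[el] <- counts[el] + 1
  }
  off <- counts[row(counts) != col(counts)]
  expect_gt(stats::chisq.test(off)$p.value, 0.001)
})

test_that("euclidean rankings concentrate edges per the rank PMF", {
  # with distinct 1-D attributes and k=1, the position of each chosen
  # target must follow the 1/(H_{n-1} i) law
  n <- 8
  attrs <- data.frame(a = seq_len(n))
  spec <- distance_spec("euclidean1d", bindings = "a")
  set.seed(77)
  pos_counts <- numeric(n - 1)
  for (rep in 1:1500) {
    el <- igraph::as_edgelist(
      priority_rank_generate(n, 1, spec, attrs = attrs), names = FALSE)
    for (r in seq_len(nrow(el))) {
      src <- el[r, 1]; tgt <- el[r, 2]
      cand <- setdiff(1:n, src)
      pos <- competition_positions(abs(attrs$a[src] - attrs$a[cand]))
      p <- pos[cand == tgt]
      pos_counts[p] <- pos_counts[p] + 1
    }
  }
  # expected counts: ties at the two equidistant neighbors make the exact
  # law source-dependent, so pool the per-source PMFs
  expected <- numeric(n - 1)
  for (src in 1:n) {
    cand <- setdiff(1:n, src)
    pmf <- selection_pmf(competition_positions(abs(attrs$a[src] - attrs$a[cand])))
    for (i in seq_along(cand)) {
      expected[pmf$positions[i]] <- expected[pmf$positions[i]] +
        pmf$probabilities[i] / n
    }
  }
  emp <- pos_counts / sum(pos_counts)
  keep <- expected > 0
  expect_gt(stats::chisq.test(pos_counts[keep],
                              p = expected[keep] / sum(expected[keep]))$p.value,
            0.001)
  # nearest-vs-median probability ratio per the rank law
  expect_gt(emp[1] / emp[4], expected[1] / expected[4] * 0.7)
})

test_that("dynamic degree distance concentrates degree relative to random", {
  share <- function(spec, s) {
    g <- priority_rank_generate(50, 3, spec, seed = s, simplify = TRUE)
    deg <- sort(igraph::degree(g), decreasing = TRUE)
    sum(deg[1:5]) / sum(deg)
  }
  deg_share <- mean(vapply(1:20, function(s)
    share(distance_spec("degree", mode = "dynamic"), s), numeric(1)))
  rnd_share <- mean(vapply(1:20, function(s)
    share(distance_spec("random"), 100 + s), numeric(1)))
  expect_gt(deg_share, rnd_share)
})

test_that("rewiring preserves out-degrees and simplicity", {
  g <- priority_rank_generate(30, 3, distance_spec("random"),
                              p_rw = 1, seed = 8)
  expect_true(all(igraph::degree(g, mode = "out") == 3))
  expect_false(igraph::any_multiple(g))
  expect_equal(sum(igraph::which_loop(g)), 0)
})

test_that("reference generators match their defining recurrences", {
  g0 <- dgm_hierarchical(0)
  expect_equal(c(igraph::vcount(g0), igraph::ecount(g0)), c(2, 1))
  g5 <- dgm_hierarchical(5)
  expect_equal(igraph::vcount(g5), 123)
  expect_equal(igraph::ecount(g5), 243)

  ec <- mean(vapply(1:5, function(s)
    igraph::ecount(erdos_renyi(50, 0.4, seed = s)), numeric(1)))
  sd3 <- 3 * sqrt(1225 * 0.4 * 0.6 / 5)
  expect_lt(abs(ec - 490), sd3)

  ba <- barabasi_albert(50, 3, seed = 1)
  expect_equal(igraph::vcount(ba), 50)
  expect_equal(igraph::ecount(ba), 3 + 47 * 3)  # K_3 seed + 3 per arrival

  ws <- watts_strogatz(50, 3, 0.01, seed = 1)
  expect_equal(igraph::vcount(ws), 50)
  expect_true(all(igraph::degree(ws) > 0))

  ff <- forest_fire(50, 1, 0.3, seed = 1)
  expect_equal(igraph::vcount(ff), 50)

  expect_error(erdos_renyi(10, 1.4), "\\[0,1\\]")
})

test_that("the disassortative reference terminates below the threshold", {
  g <- disassortative_reference(100, seed = 5)
  expect_lt(igraph::assortativity_degree(g), -0.4)
})

test_that("process networks follow their defining selection rules", {
  g1 <- process_network("N1", n = 40, m = 4, seed = 1)
  expect_false(igraph::is_directed(g1))
  attrs <- vertex_attributes(g1)
  dmat <- as.matrix(dist(attrs[, c("X", "Y")]))
  # every simplified edge comes from at least one endpoint's 4-NN set
  el <- igraph::as_edgelist(g1, names = FALSE)
  in_knn <- function(v, u, k) {
    rank(dmat[v, -v])[match(u, setdiff(1:40, v))] <= k
  }
  expect_true(all(apply(el, 1, function(e)
    in_knn(e[1], e[2], 4) || in_knn(e[2], e[1], 4))))

  # N3 with m = 2: each vertex keeps an edge to its nearest and farthest
  g3 <- process_network("N3", n = 30, m = 2, seed = 2)
  a3 <- vertex_attributes(g3)
  d3 <- as.matrix(dist(a3[, c("X", "Y")])); diag(d3) <- NA
  for (v in c(1, 10, 30)) {
    expect_true(igraph::are_adjacent(g3, v, which.min(d3[v, ])))
    expect_true(igraph::are_adjacent(g3, v, which.max(d3[v, ])))
  }

  expect_error(process_network("N1", n = 10, m = 10), "smaller")
  expect_error(process_network("N3", n = 10, m = 3), "even")
})
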