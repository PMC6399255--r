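# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementation paths.

# competition rank: 1 + number of strictly smaller values
oracle_positions <- function(d) {
  vapply(d, function(x) 1L + sum(d < x), integer(1))
}

# rank-selection probabilities straight from the definition
oracle_pmf <- function(positions) {
  w <- 1 / positions
  w / sum(w)
}

# two-sample K-S statistic by a double loop over all sample points
oracle_ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# triangle count by exhaustive triple enumeration on an adjacency matrix
oracle_triangles <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(simplify_network(g)))
  n <- nrow(A)
  if (n < 3) return(0L)
  count <- 0L
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (A[i, j] && A[j, k] && A[i, k]) count <- count + 1L
  }
  count
}

# global clustering from the triangle/triple definition
oracle_transitivity <- function(g) {
  gu <- simplify_network(g)
  deg <- igraph::degree(gu)
  triples <- sum(choose(deg, 2))
  if (triples == 0) return(0)
  3 * oracle_triangles(gu) / triples
}

# exact inclusion probabilities of a 2-draw without-replacement scheme by
# enumerating all ordered draw pairs
oracle_inclusion_2 <- function(p) {
  m <- length(p)
  incl <- numeric(m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    pr <- p[i] * p[j] / (1 - p[i])
    incl[i] <- incl[i] + pr
    incl[j] <- incl[j] + pr
  }
  incl
}

# small deterministic attribute table used across distance tests
fixture_attrs <- function(n, seed = 421) {
  set.seed(seed)
  data.frame(
    x = stats::runif(n),
    y = stats::runif(n),
    grade = as.integer(sample(1:5, n, replace = TRUE)),
    group = factor(sample(c("a", "b", "c"), n, replace = TRUE))
  )
}
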