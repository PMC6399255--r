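#' Generate a network with the Priority Rank model
#'
#' All `n` vertices exist from the start and take turns in a seeded random
#' order. On its turn a vertex computes its distance to every other vertex,
#' ranks the candidates by competition ranking, converts the ranking into
#' the rank-based selection PMF (probability of position \eqn{i}
#' proportional to \eqn{1/i}) and draws its targets without replacement, so
#' a source never draws the same target twice and the result is a simple
#' directed graph. Centrality-based distance families in dynamic mode see
#' the partial edge set as it stood at the start of the source's turn.
#'
#' An optional post-pass rewires each directed edge independently with
#' probability `p_rw` to a uniformly chosen new target (avoiding self-loops
#' and duplicate edges of the same source).
#'
#' @param n number of vertices (ignored when `attrs` is given with rows).
#' @param k out-degree rule: a single constant, or a vector of per-vertex
#'   out-degrees (e.g. sampled from an empirical out-degree distribution).
#' @param spec a [distance_spec()].
#' @param attrs optional vertex attribute table.
#' @param schedule `"per_vertex"` (each vertex draws all its targets on its
#'   single turn; default) or `"round_robin"` (one edge per vertex per
#'   round).
#' @param p_rw probability of uniformly rewiring each edge afterwards.
#' @param simplify if `TRUE`, merge reciprocal edges and drop direction.
#' @param seed optional integer seed.
#' @return An igraph object (directed unless `simplify = TRUE`) carrying
#'   the vertex attributes.
#' @examples
#' attrs <- data.frame(a = runif(30))
#' g <- priority_rank_generate(30, k = 3,
#'   spec = distance_spec("euclidean1d", bindings = "a"),
#'   attrs = attrs, seed = 1)
#' @export
priority_rank_generate <- function(n, k, spec, attrs = NULL,
                                   schedule = c("per_vertex", "round_robin"),
                                   p_rw = 0, simplify = FALSE, seed = NULL) {
  schedule <- match.arg(schedule)
  if (!is.null(attrs)) n <- nrow(attrs)
  if (n < 2) stop("need at least 2 vertices", call. = FALSE)
  if (p_rw < 0 || p_rw > 1) stop("`p_rw` must be in [0,1]", call. = FALSE)
  kvec <- if (length(k) == 1L) rep.int(as.integer(k), n) else as.integer(k)
  if (length(kvec) != n || any(kvec < 1)) {
    stop("`k` must be a positive constant or one out-degree per vertex",
         call. = FALSE)
  }
  if (any(kvec > n - 1)) {
    stop("assigned out-degree exceeds n - 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  g <- pr_graph(n, attrs = attrs, directed = TRUE)
  turn_order <- sample.int(n)

  draw_for <- function(g, v, k_draw, exclude) {
    candidates <- setdiff(seq_len(n), c(v, exclude))
    d <- evaluate_distance(spec, g, v, candidates)
    pmf <- selection_pmf(competition_positions(d))
    sample_targets(pmf, k_draw, candidates)
  }

  if (schedule == "per_vertex") {
    for (v in turn_order) {
      targets <- draw_for(g, v, kvec[v], integer(0))
      g <- igraph::add_edges(g, rbind(v, targets))
    }
  } else {
    chosen <- vector("list", n)
    for (round in seq_len(max(kvec))) {
      for (v in turn_order) {
        if (kvec[v] < round) next
        t1 <- draw_for(g, v, 1L, chosen[[v]])
        chosen[[v]] <- c(chosen[[v]], t1)
        g <- igraph::add_edges(g, c(v, t1))
      }
    }
  }

  if (p_rw > 0) g <- rewire_uniform(g, p_rw)
  if (simplify) g <- simplify_network(g)
  g
}

# rewire each directed edge with probability p to a uniform new target,
# keeping the graph simple and loop-free
rewire_uniform <- function(g, p) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  hit <- which(stats::runif(nrow(el)) < p)
  for (e in hit) {
    src <- el[e, 1]
    taken <- el[el[, 1] == src, 2]
    free <- setdiff(seq_len(n), c(src, taken))
    if (length(free) == 0) next
    el[e, 2] <- if (length(free) == 1) free else sample(free, 1)
  }
  g2 <- pr_graph(n, directed = igraph::is_directed(g), edges = el)
  for (a in igraph::vertex_attr_names(g)) {
    g2 <- igraph::set_vertex_attr(g2, a, value = igraph::vertex_attr(g, a))
  }
  g2
}

#' Reference network generators
#'
#' Standard generative models used as comparison baselines:
#' Erdos-Renyi \eqn{G(n,p)}, the Watts-Strogatz ring with rewiring, the
#' Albert-Barabasi preferential attachment model seeded with a complete
#' graph on `n0` vertices, the Leskovec forest fire model (each new vertex
#' picks `k` uniform ambassadors and burns recursively with probability
#' `p_burn`), the Dorogovtsev-Goltsev-Mendes construction (every edge
#' spawns a new vertex attached to both its ends at every step, so
#' \eqn{V_{t+1} = V_t + E_t}, \eqn{E_{t+1} = 3 E_t} from \eqn{(V_0, E_0) =
#' (2, 1)}), and a bespoke disassortative procedure that wires three vertex
#' strata with very different out-degree budgets until the degree
#' assortativity drops below `threshold`.
#'
#' @param n number of vertices.
#' @param p,p_rewire,p_burn model-specific probabilities.
#' @param k neighbors (WS: per side), edges per new vertex (BA), or
#'   ambassadors (forest fire).
#' @param n0 size of the initial complete graph (BA).
#' @param t number of growth steps (DGM).
#' @param threshold stop threshold on assortativity (disassortative model).
#' @param max_iter safety cap on disassortative iterations.
#' @param seed optional integer seed.
#' @return An igraph object.
#' @name reference_generators
NULL

#' @rdname reference_generators
#' @export
erdos_renyi <- function(n, p, seed = NULL) {
  if (p < 0 || p > 1) stop("`p` must be in [0,1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  igraph::sample_gnp(n, p, directed = FALSE)
}

#' @rdname reference_generators
#' @export
watts_strogatz <- function(n, k = 3, p_rewire = 0.01, seed = NULL) {
  if (p_rewire < 0 || p_rewire > 1) {
    stop("`p_rewire` must be in [0,1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  igraph::sample_smallworld(1, n, k, p_rewire)
}

#' @rdname reference_generators
#' @export
barabasi_albert <- function(n, k = 3, n0 = k, seed = NULL) {
  if (n0 < k) stop("`n0` must be at least `k`", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  igraph::sample_pa(n, power = 1, m = k, directed = FALSE,
                    start.graph = igraph::make_full_graph(n0))
}

#' @rdname reference_generators
#' @export
forest_fire <- function(n, k = 1, p_burn = 0.3, seed = NULL) {
  if (p_burn < 0 || p_burn > 1) stop("`p_burn` must be in [0,1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  igraph::sample_forestfire(n, fw.prob = p_burn, ambs = k, directed = FALSE)
}

#' @rdname reference_generators
#' @export
dgm_hierarchical <- function(t) {
  if (length(t) != 1L || t < 0 || t != floor(t)) {
    stop("`t` must be a nonnegative integer", call. = FALSE)
  }
  el <- matrix(c(1L, 2L), 1, 2)
  n <- 2L
  for (step in seq_len(t)) {
    new_v <- n + seq_len(nrow(el))
    el <- rbind(el,
                cbind(el[, 1], new_v),
                cbind(el[, 2], new_v))
    n <- n + as.integer(nrow(el) / 3)
  }
  pr_graph(n, directed = FALSE, edges = el)
}

#' @rdname reference_generators
#' @export
disassortative_reference <- function(n = 100, threshold = -0.4,
                                     max_iter = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  el <- matrix(integer(0), 0, 2)
  for (iter in seq_len(max_iter)) {
    for (v in 1:10) {
      m <- sample(30:40, 1)
      el <- rbind(el, cbind(v, sample(50:n, m, replace = TRUE)))
    }
    for (v in 11:50) {
      m <- sample(0:15, 1)
      if (m > 0) el <- rbind(el, cbind(v, sample.int(n, m, replace = TRUE)))
    }
    for (v in 51:n) {
      m <- sample(0:2, 1)
      if (m > 0) el <- rbind(el, cbind(v, sample.int(n, m, replace = TRUE)))
    }
    el <- unique(el[el[, 1] != el[, 2], , drop = FALSE])
    g <- simplify_network(pr_graph(n, directed = FALSE, edges = el))
    r <- suppressWarnings(igraph::assortativity_degree(g))
    if (is.finite(r) && r < threshold) return(g)
  }
  g
}

#' Process networks driven by planar proximity
#'
#' Builds the three coordinate-based test processes: each of `n` vertices
#' gets two uniform(0,1) coordinates, then
#' \describe{
#'   \item{N1}{links its `m` nearest neighbors (euclidean distance),}
#'   \item{N2}{draws `m` targets uniformly from its `k_pool` nearest,}
#'   \item{N3}{links its `m/2` nearest and `m/2` farthest neighbors.}
#' }
#' The directed result is simplified to an undirected graph; the
#' coordinates remain attached as attributes `X`, `Y`.
#'
#' @param variant `"N1"`, `"N2"` or `"N3"`.
#' @param n number of vertices.
#' @param m edges created per vertex (even for N3).
#' @param k_pool candidate-pool size for N2.
#' @param seed optional integer seed.
#' @return An undirected igraph object with `X`, `Y` vertex attributes.
#' @export
process_network <- function(variant = c("N1", "N2", "N3"), n = 100, m = 4,
                            k_pool = 10, seed = NULL) {
  variant <- match.arg(variant)
  if (m >= n) stop("`m` must be smaller than `n`", call. = FALSE)
  if (variant == "N3" && m %% 2 != 0) {
    stop("`m` must be even for N3", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  coords <- data.frame(X = stats::runif(n), Y = stats::runif(n))
  dmat <- as.matrix(stats::dist(coords))
  el <- do.call(rbind, lapply(seq_len(n), function(v) {
    ord <- order(dmat[v, -v]) # candidate order, nearest first
    cand <- seq_len(n)[-v][ord]
    targets <- switch(variant,
      N1 = cand[seq_len(m)],
      N2 = sample(cand[seq_len(k_pool)], m),
      N3 = c(cand[seq_len(m / 2)], rev(cand)[seq_len(m / 2)])
    )
    cbind(v, targets)
  }))
  simplify_network(pr_graph(n, attrs = coords, directed = TRUE, edges = el))
}
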