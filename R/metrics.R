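#' Vertex centrality vector
#'
#' Computes one of the four centrality measures used throughout the
#' package. Degree counts adjacent vertices; betweenness counts shortest
#' paths through a vertex; closeness is the conventional inverse mean
#' shortest-path distance within the vertex's reachable set; pagerank is
#' the stationary importance with damping 0.85 (values sum to 1).
#'
#' @param g an igraph object.
#' @param measure `"degree"`, `"betweenness"`, `"closeness"` or
#'   `"pagerank"`.
#' @param orientation `"all"`, `"in"` or `"out"` (directed graphs only).
#' @return A list with `measure`, `orientation` and numeric `values` (one
#'   per vertex).
#' @export
centrality <- function(g, measure = c("degree", "betweenness", "closeness",
                                      "pagerank"),
                       orientation = c("all", "in", "out")) {
  measure <- match.arg(measure)
  orientation <- match.arg(orientation)
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  values <- switch(measure,
    degree = igraph::degree(g, mode = orientation),
    betweenness = igraph::betweenness(g, directed = igraph::is_directed(g)),
    closeness = {
      cl <- suppressWarnings(
        igraph::closeness(g, mode = orientation, normalized = TRUE)
      )
      cl[is.na(cl)] <- 0 # isolated vertices reach nothing
      cl
    },
    pagerank = igraph::page_rank(g, damping = 0.85)$vector
  )
  list(measure = measure, orientation = orientation,
       values = as.numeric(values))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Maximum gap between the empirical CDFs of two samples, with the
#' asymptotic two-sided p-value. Ties (ubiquitous in discrete degree
#' samples) are tolerated; the asymptotic formula is used regardless.
#'
#' @param a,b numeric samples.
#' @return A list with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("samples must be non-empty", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = min(1, unname(res$p.value)))
}

freeman_centralization <- function(g) {
  n <- igraph::vcount(g)
  if (n < 3) return(0)
  deg <- igraph::degree(g, mode = "all")
  sum(max(deg) - deg) / ((n - 1) * (n - 2))
}

#' Scalar profile of a network
#'
#' Computes the scalar comparison metrics: diameter `d` and mean shortest
#' path `L` (both on the largest connected component of the undirected
#' simplified view), density `rho` (relative to the maximum possible for
#' the graph's directedness), reciprocity `r` (fraction of directed edges
#' whose reciprocal exists; 1 by convention for undirected graphs), degree
#' assortativity, transitivity (global clustering coefficient), and
#' Freeman centralization of the degree distribution.
#'
#' @param g an igraph object.
#' @return A named list of scalars.
#' @export
profile_network <- function(g) {
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  gu <- simplify_network(g)
  comp <- igraph::components(gu)
  lcc <- igraph::induced_subgraph(
    gu, which(comp$membership == which.max(comp$csize))
  )
  r <- if (igraph::is_directed(g)) {
    rec <- igraph::reciprocity(g)
    if (is.nan(rec)) 0 else rec
  } else 1
  assort <- suppressWarnings(igraph::assortativity_degree(gu))
  trans <- igraph::transitivity(gu, type = "global")
  list(
    d = if (igraph::vcount(lcc) > 1) igraph::diameter(lcc, directed = FALSE) else 0,
    density = igraph::edge_density(g),
    L = if (igraph::vcount(lcc) > 1) {
      igraph::mean_distance(lcc, directed = FALSE)
    } else 0,
    r = r,
    assortativity = if (is.finite(assort)) assort else 0,
    transitivity = if (is.finite(trans)) trans else 0,
    centralization = freeman_centralization(gu)
  )
}

#' Compare a generated network against an original
#'
#' The comparison the whole package optimizes: two-sample K-S tests on the
#' degree, betweenness and closeness centrality distributions (p-values
#' `p_D`, `p_B`, `p_C`; the null "both samples come from one distribution"
#' is rejected below `alpha`), plus the scalar profiles of both graphs with
#' pass flags for scalars regenerated within +/-10% of the original value.
#' The generated graph is coerced to the original's directedness first.
#'
#' @param g_generated,g_original igraph objects.
#' @param alpha significance level for the K-S tests.
#' @return An object of class `pr_comparison`: K-S p-values and statistics,
#'   both profiles, and logical pass flags.
#' @export
compare_networks <- function(g_generated, g_original, alpha = 0.05) {
  if (!igraph::is_directed(g_original) && igraph::is_directed(g_generated)) {
    g_generated <- simplify_network(g_generated)
  }
  ks <- lapply(c(degree = "degree", betweenness = "betweenness",
                 closeness = "closeness"), function(m) {
    ks_two_sample(centrality(g_generated, m)$values,
                  centrality(g_original, m)$values)
  })
  prof_gen <- profile_network(g_generated)
  prof_orig <- profile_network(g_original)
  scalar_ok <- mapply(function(gen, orig) {
    if (orig == 0) return(abs(gen) < 1e-12)
    abs(gen - orig) <= 0.1 * abs(orig)
  }, prof_gen, prof_orig)
  structure(
    list(
      p_D = ks$degree$p_value, p_B = ks$betweenness$p_value,
      p_C = ks$closeness$p_value,
      ks_stat = vapply(ks, `[[`, numeric(1), "statistic"),
      ks_pass = vapply(ks, function(x) x$p_value >= alpha, logical(1)),
      profile_generated = prof_gen,
      profile_original = prof_orig,
      scalar_pass = scalar_ok,
      alpha = alpha
    ),
    class = "pr_comparison"
  )
}

#' @export
print.pr_comparison <- function(x, ...) {
  cat("Network comparison (alpha =", x$alpha, ")\n")
  cat(sprintf("  K-S p-values: p_D=%.3f p_B=%.3f p_C=%.3f (%d/3 retained)\n",
              x$p_D, x$p_B, x$p_C, sum(x$ks_pass)))
  sc <- data.frame(
    generated = unlist(x$profile_generated),
    original = unlist(x$profile_original),
    within_10pct = unname(x$scalar_pass)
  )
  print(round_df(sc, 4))
  invisible(x)
}

round_df <- function(df, digits) {
  df[] <- lapply(df, function(x) if (is.numeric(x)) round(x, digits) else x)
  df
}
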