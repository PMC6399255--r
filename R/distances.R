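#' Distance function specifications
#'
#' A distance specification describes one member of the catalogue of
#' vertex-to-vertex distance functions driving priority attachment. The
#' supported families are:
#'
#' \describe{
#'   \item{random}{independent draw per (source, candidate) evaluation;
#'     local rankings are random permutations. Only rank order matters, so
#'     draws are taken uniform on (0,1) (rank-equivalent to any continuous
#'     law such as N(mu, sigma)).}
#'   \item{degree, betweenness, closeness, pagerank}{\eqn{1/(C(v_j)+\epsilon)}
#'     for the corresponding centrality of the candidate; `mode = "dynamic"`
#'     recomputes centralities on the growing graph at each source's turn,
#'     `mode = "reference"` freezes them from a reference graph.}
#'   \item{euclidean1d}{\eqn{|a_i - a_j|} on one bound numeric attribute.}
#'   \item{euclidean2d}{euclidean distance on two bound numeric attributes.}
#'   \item{cosine}{\eqn{1 - \cos(v_i, v_j)} on the bound numeric attributes.}
#'   \item{aggregate}{weighted sum of per-attribute kernels: absolute
#'     difference for numeric/ordinal columns, 0/1 mismatch for categorical.}
#'   \item{hierarchical}{\eqn{\alpha D_E + (1-\alpha) D_H}, where
#'     \eqn{D_H} is the absolute difference of ranks of totally ordered
#'     class labels.}
#'   \item{disassortative}{\eqn{\max(0,\; deg^* - deg(v_i)/deg(v_j))} with
#'     \eqn{deg^*} the current maximum degree; favors attachment between
#'     dissimilar degrees.}
#'   \item{toy_age_sex}{absolute age difference, plus 10 when the two
#'     vertices differ in sex (the package's worked toy example).}
#'   \item{linear_regression, naive_bayes}{learned distances; see
#'     [fit_linear_regression_distance()] and [fit_naive_bayes_distance()].}
#' }
#'
#' @param family one of the family names above.
#' @param bindings character vector of attribute columns the family reads.
#' @param mode `"dynamic"` or `"reference"` for centrality families.
#' @param orientation `"all"`, `"in"` or `"out"`: which degree/centrality
#'   orientation centrality families use on directed graphs.
#' @param eps smoothing constant used wherever a formula divides by a
#'   possibly-zero quantity or needs a positive floor.
#' @param alpha mixing weight of the hierarchical family.
#' @param class_column label column for the hierarchical family (must be an
#'   ordered set: ordered factor, or numeric/integer levels).
#' @param weights per-attribute weights for the aggregate family (recycled
#'   to equal weights when `NULL`).
#' @param model fitted [fit_linear_regression_distance()] /
#'   [fit_naive_bayes_distance()] object for learned families.
#' @param reference igraph object whose centralities are frozen when
#'   `mode = "reference"`.
#' @return An object of class `pr_distance`.
#' @export
distance_spec <- function(family,
                          bindings = NULL,
                          mode = c("dynamic", "reference"),
                          orientation = c("all", "in", "out"),
                          eps = 1e-6,
                          alpha = 0.5,
                          class_column = NULL,
                          weights = NULL,
                          model = NULL,
                          reference = NULL) {
  family <- match.arg(family, c(
    "random", "degree", "betweenness", "closeness", "pagerank",
    "euclidean1d", "euclidean2d", "cosine", "aggregate", "hierarchical",
    "disassortative", "toy_age_sex", "linear_regression", "naive_bayes"
  ))
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  spec <- structure(
    list(family = family, bindings = bindings, mode = mode,
         orientation = orientation, eps = eps, alpha = alpha,
         class_column = class_column, weights = weights, model = model,
         reference_values = NULL),
    class = "pr_distance"
  )
  if (family %in% c("degree", "betweenness", "closeness", "pagerank") &&
      mode == "reference") {
    if (is.null(reference)) {
      stop("reference mode requires a `reference` graph", call. = FALSE)
    }
    spec$reference_values <- centrality(reference, family, orientation)$values
  }
  if (family == "hierarchical" && is.null(class_column)) {
    stop("hierarchical family requires `class_column`", call. = FALSE)
  }
  spec
}

#' @export
print.pr_distance <- function(x, ...) {
  cat("<pr_distance> family:", x$family,
      if (!is.null(x$bindings)) paste0("[", paste(x$bindings, collapse = ","), "]"),
      if (x$family %in% c("degree", "betweenness", "closeness", "pagerank"))
        paste0("(", x$mode, ", ", x$orientation, ")"),
      "\n")
  invisible(x)
}

bound_numeric <- function(g, spec, need = NULL) {
  attrs <- vertex_attributes(g)
  cols <- spec$bindings
  if (is.null(cols)) {
    cols <- names(attrs)[vapply(attrs, is.numeric, logical(1))]
  }
  missing <- setdiff(cols, names(attrs))
  if (length(missing) > 0) {
    stop("attribute column(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(need) && length(cols) < need) {
    stop("family needs ", need, " bound attribute column(s)", call. = FALSE)
  }
  attrs[, cols, drop = FALSE]
}

centrality_values <- function(g, spec) {
  if (spec$mode == "reference") {
    if (is.null(spec$reference_values)) {
      stop("reference centrality values not attached to spec", call. = FALSE)
    }
    return(spec$reference_values)
  }
  centrality(g, spec$family, spec$orientation)$values
}

#' Evaluate a distance specification
#'
#' Computes `D(source, candidate)` for each candidate vertex against the
#' current graph state. Every family returns finite nonnegative values;
#' `D(v, v) = 0` by construction (the source never appears among its own
#' candidates during generation).
#'
#' @param spec a [distance_spec()].
#' @param g the current graph state (igraph with vertex attributes).
#' @param source source vertex id (1-based).
#' @param candidates integer vector of candidate vertex ids.
#' @return Numeric vector of distances aligned with `candidates`.
#' @export
evaluate_distance <- function(spec, g, source, candidates) {
  stopifnot(inherits(spec, "pr_distance"))
  m <- length(candidates)
  out <- switch(spec$family,
    random = stats::runif(m),
    degree = ,
    betweenness = ,
    closeness = ,
    pagerank = {
      cv <- centrality_values(g, spec)
      1 / (cv[candidates] + spec$eps)
    },
    euclidean1d = {
      a <- bound_numeric(g, spec, need = 1)[[1]]
      abs(a[source] - a[candidates])
    },
    euclidean2d = {
      a <- bound_numeric(g, spec, need = 2)
      sqrt((a[[1]][source] - a[[1]][candidates])^2 +
           (a[[2]][source] - a[[2]][candidates])^2)
    },
    cosine = {
      a <- as.matrix(bound_numeric(g, spec, need = 1))
      vi <- a[source, ]
      ni <- sqrt(sum(vi^2))
      nj <- sqrt(rowSums(a[candidates, , drop = FALSE]^2))
      sim <- as.numeric(a[candidates, , drop = FALSE] %*% vi) /
        (ni * nj + spec$eps)
      pmax(0, 1 - sim)
    },
    aggregate = aggregate_distance(spec, g, source, candidates),
    hierarchical = hierarchical_distance_eval(spec, g, source, candidates),
    disassortative = disassortative_distance(g, source, candidates, spec$eps),
    toy_age_sex = {
      attrs <- vertex_attributes(g)
      d <- abs(attrs$age[source] - attrs$age[candidates])
      d + 10 * (attrs$sex[candidates] != attrs$sex[source])
    },
    linear_regression = ,
    naive_bayes = {
      if (is.null(spec$model)) {
        stop("learned family requires a fitted `model`", call. = FALSE)
      }
      predict_distance(spec$model, vertex_attributes(g), source, candidates,
                       eps = spec$eps)
    }
  )
  out <- as.numeric(out)
  if (length(out) != m || any(!is.finite(out))) {
    stop("distance evaluation produced invalid values", call. = FALSE)
  }
  pmax(out, 0)
}

aggregate_distance <- function(spec, g, source, candidates) {
  attrs <- vertex_attributes(g)
  cols <- spec$bindings
  if (is.null(cols)) cols <- names(attrs)
  missing <- setdiff(cols, names(attrs))
  if (length(missing) > 0) {
    stop("attribute column(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  w <- spec$weights
  if (is.null(w)) w <- rep(1 / length(cols), length(cols))
  if (length(w) != length(cols)) {
    stop("`weights` must match the number of bound columns", call. = FALSE)
  }
  total <- numeric(length(candidates))
  for (k in seq_along(cols)) {
    x <- attrs[[cols[k]]]
    kernel <- if (is.numeric(x)) {
      abs(x[source] - x[candidates])
    } else {
      as.numeric(x[candidates] != x[source])
    }
    total <- total + w[k] * kernel
  }
  total
}

hierarchical_distance_eval <- function(spec, g, source, candidates) {
  attrs <- vertex_attributes(g)
  cls <- attrs[[spec$class_column]]
  if (is.null(cls)) {
    stop("class column not found: ", spec$class_column, call. = FALSE)
  }
  if (is.ordered(cls) || is.numeric(cls)) {
    r <- as.numeric(cls)
  } else {
    stop("hierarchical class labels must be totally ordered ",
         "(ordered factor or numeric)", call. = FALSE)
  }
  de <- {
    num <- setdiff(spec$bindings, spec$class_column)
    if (length(num) == 0) {
      num <- setdiff(names(attrs)[vapply(attrs, is.numeric, logical(1))],
                     spec$class_column)
    }
    a <- as.matrix(attrs[, num, drop = FALSE])
    sqrt(rowSums((a[candidates, , drop = FALSE] -
                  matrix(a[source, ], length(candidates), ncol(a),
                         byrow = TRUE))^2))
  }
  dh <- abs(r[source] - r[candidates])
  d <- spec$alpha * de + (1 - spec$alpha) * dh
  # positivity for i != j: deterministic jitter keyed by the vertex id pair
  zero <- d == 0
  if (any(zero)) {
    d[zero] <- 1e-12 * (1 + abs(source - candidates[zero]))
  }
  d
}

#' Disassortative degree-ratio distance
#'
#' \eqn{D(v_i, v_j) = \max(0,\; deg^* - deg(v_i)/deg(v_j))}, where
#' \eqn{deg^*} is the current maximum total degree and a zero candidate
#' degree is smoothed by `eps`. The distance is small when the source's
#' degree dwarfs the candidate's, so high-degree sources preferentially
#' attach to low-degree candidates, producing disassortative networks.
#'
#' @param g current graph state.
#' @param source source vertex id.
#' @param candidates candidate vertex ids.
#' @param eps smoothing constant for zero candidate degree.
#' @return Numeric vector of distances.
#' @export
disassortative_distance <- function(g, source, candidates, eps = 1e-6) {
  deg <- igraph::degree(g, mode = "all")
  deg_star <- max(deg)
  denom <- ifelse(deg[candidates] == 0, eps, deg[candidates])
  pmax(0, deg_star - deg[source] / denom)
}
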