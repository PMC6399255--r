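#' Build an adjacency-derived training set
#'
#' Turns a graph plus its vertex attribute table into labeled pairs for
#' learned distance functions. Each row concatenates the attribute tuples
#' of both endpoints (`src_*` then `dst_*` columns). Positive cases are all
#' ordered adjacent pairs; negative cases are non-adjacent ordered pairs,
#' sampled uniformly at `negative_ratio` times the number of positives.
#' For graphs with at most 200 vertices all non-adjacent pairs are
#' enumerated and sampled without replacement; larger graphs use rejection
#' sampling.
#'
#' @param g an igraph object.
#' @param attrs vertex attribute table; defaults to the graph's own.
#' @param negative_ratio positive multiplier of the positive count.
#' @param seed optional integer seed for negative sampling.
#' @return A data frame with `src_*`/`dst_*` attribute columns, a `label`
#'   factor (`edge`/`nonedge`) and `src`/`dst` id columns.
#' @export
build_training_set <- function(g, attrs = vertex_attributes(g),
                               negative_ratio = 1, seed = NULL) {
  if (negative_ratio <= 0) {
    stop("`negative_ratio` must be positive", call. = FALSE)
  }
  n <- igraph::vcount(g)
  if (nrow(attrs) != n) {
    stop("attribute table must cover all vertices", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (!igraph::is_directed(g) && nrow(el) > 0) {
    el <- rbind(el, el[, 2:1, drop = FALSE])
  }
  el <- unique(el)
  n_pos <- nrow(el)
  n_neg_want <- round(negative_ratio * n_pos)

  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  if (n <= 200) {
    all_pairs <- expand.grid(src = seq_len(n), dst = seq_len(n))
    all_pairs <- all_pairs[all_pairs$src != all_pairs$dst, ]
    is_edge <- adj[cbind(all_pairs$src, all_pairs$dst)] > 0
    negs <- all_pairs[!is_edge, , drop = FALSE]
    if (nrow(negs) > n_neg_want) {
      negs <- negs[sample.int(nrow(negs), n_neg_want), , drop = FALSE]
    }
  } else {
    negs <- matrix(NA_integer_, 0, 2)
    while (nrow(negs) < n_neg_want) {
      cand <- cbind(sample.int(n, n_neg_want, replace = TRUE),
                    sample.int(n, n_neg_want, replace = TRUE))
      cand <- cand[cand[, 1] != cand[, 2] & adj[cand] == 0, , drop = FALSE]
      negs <- unique(rbind(negs, cand))
    }
    negs <- data.frame(src = negs[seq_len(n_neg_want), 1],
                       dst = negs[seq_len(n_neg_want), 2])
  }

  pair_rows <- function(idx, label) {
    if (NROW(idx) == 0) return(NULL)
    src_attrs <- attrs[idx[, 1], , drop = FALSE]
    dst_attrs <- attrs[idx[, 2], , drop = FALSE]
    names(src_attrs) <- paste0("src_", names(attrs))
    names(dst_attrs) <- paste0("dst_", names(attrs))
    cbind(src_attrs, dst_attrs,
          data.frame(label = label, src = idx[, 1], dst = idx[, 2]))
  }
  out <- rbind(pair_rows(el, "edge"),
               pair_rows(as.matrix(negs[, c("src", "dst")]), "nonedge"))
  rownames(out) <- NULL
  out$label <- factor(out$label, levels = c("edge", "nonedge"))
  out
}

feature_columns <- function(pairs) {
  grep("^(src|dst)_", names(pairs), value = TRUE)
}

#' Fit a linear-regression distance
#'
#' Least-squares fit on the concatenated-attribute design, regressing the
#' non-adjacency indicator (0 for edge pairs, 1 for non-edge pairs), so
#' that predicted values behave as distances: small for likely edges.
#' Predictions are floored at `eps` when evaluated, keeping distances
#' positive. Rank-deficient designs fall back on the pivoted least-squares
#' solution with a warning.
#'
#' @param pairs training rows from [build_training_set()].
#' @param eps positive floor applied to predictions.
#' @return An object of class `pr_learned` with the fit, an in-sample
#'   separation AUC (probability a non-edge pair outranks an edge pair),
#'   and a `degenerate` flag for constant predictors.
#' @export
fit_linear_regression_distance <- function(pairs, eps = 1e-6) {
  fc <- feature_columns(pairs)
  df <- pairs[, fc, drop = FALSE]
  df$.y <- as.numeric(pairs$label == "nonedge")
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    warning("rank-deficient design; pivoted least-squares solution used",
            call. = FALSE)
  }
  pred <- suppressWarnings(stats::predict(fit, newdata = df))
  model <- structure(
    list(kind = "linear_regression", fit = fit, features = fc, eps = eps,
         degenerate = stats::var(pred) < 1e-12,
         auc = pair_auc(pred, pairs$label)),
    class = "pr_learned"
  )
  if (model$degenerate) {
    warning("degenerate fit: constant distance predictor", call. = FALSE)
  }
  model
}

#' Fit a naive-Bayes distance
#'
#' Naive Bayes classifier (Gaussian class-conditionals for numeric columns,
#' add-one-smoothed frequency tables for categorical ones) on the
#' concatenated-attribute design. The resulting distance is
#' \eqn{P(\mathrm{nonedge} \mid W) / (P(\mathrm{edge} \mid W) + \epsilon)},
#' small when the pair looks like an edge.
#'
#' @inheritParams fit_linear_regression_distance
#' @return An object of class `pr_learned`.
#' @export
fit_naive_bayes_distance <- function(pairs, eps = 1e-6) {
  fc <- feature_columns(pairs)
  df <- pairs[, fc, drop = FALSE]
  fit <- e1071::naiveBayes(x = df, y = pairs$label, laplace = 1)
  post <- stats::predict(fit, newdata = df, type = "raw")
  pred <- post[, "nonedge"] / (post[, "edge"] + eps)
  structure(
    list(kind = "naive_bayes", fit = fit, features = fc, eps = eps,
         degenerate = stats::var(pred) < 1e-12,
         auc = pair_auc(pred, pairs$label)),
    class = "pr_learned"
  )
}

# rank-based AUC: P(distance(nonedge) > distance(edge)) + 0.5 P(tie)
pair_auc <- function(pred, label) {
  pos <- pred[label == "nonedge"]
  neg <- pred[label == "edge"]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' @export
print.pr_learned <- function(x, ...) {
  cat("<pr_learned>", x$kind, "| in-sample separation AUC:",
      format(x$auc, digits = 3),
      if (isTRUE(x$degenerate)) "(degenerate)", "\n")
  invisible(x)
}

predict_distance <- function(model, attrs, source, candidates, eps = NULL) {
  stopifnot(inherits(model, "pr_learned"))
  if (is.null(eps)) eps <- model$eps
  src_attrs <- attrs[rep(source, length(candidates)), , drop = FALSE]
  dst_attrs <- attrs[candidates, , drop = FALSE]
  names(src_attrs) <- paste0("src_", names(attrs))
  names(dst_attrs) <- paste0("dst_", names(attrs))
  df <- cbind(src_attrs, dst_attrs)[, model$features, drop = FALSE]
  pred <- if (model$kind == "linear_regression") {
    suppressWarnings(as.numeric(stats::predict(model$fit, newdata = df)))
  } else {
    post <- stats::predict(model$fit, newdata = df, type = "raw")
    post[, "nonedge"] / (post[, "edge"] + eps)
  }
  pmax(pred, eps)
}
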