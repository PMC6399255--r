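#' Synthetic vertex attribute schemas
#'
#' `attribute_schema()` declares one column of a synthetic attribute table:
#' its name, kind (`continuous`, `ordinal` or `categorical`), generating
#' distribution (`normal`, `uniform`, `lognormal`, `exponential`) and
#' distribution parameters. `default_attribute_schema()` returns the
#' four-column preset used whenever a network carries no real features:
#' one ordinal, one categorical and two continuous columns, each fed by a
#' different one of the four distributions.
#'
#' Ordinal columns are rank-discretized draws (`levels` equal-probability
#' bins of the latent draw, so the discretization is monotone in the latent
#' value); categorical columns are quantile-binned labels.
#'
#' @param name column name.
#' @param kind one of `"continuous"`, `"ordinal"`, `"categorical"`.
#' @param dist one of `"normal"`, `"uniform"`, `"lognormal"`, `"exponential"`.
#' @param params list of distribution parameters (defaults: N(0,1), U(0,1),
#'   lognormal(0,1), Exp(1)).
#' @param levels number of ordinal levels or categorical bins.
#' @return A list of class `pr_attr_column`; `default_attribute_schema()`
#'   returns a list of four such columns.
#' @export
attribute_schema <- function(name, kind, dist, params = list(), levels = NULL) {
  kind <- match.arg(kind, c("continuous", "ordinal", "categorical"))
  dist <- match.arg(dist, c("normal", "uniform", "lognormal", "exponential"))
  if (kind != "continuous" && is.null(levels)) {
    stop("`levels` required for ordinal/categorical columns", call. = FALSE)
  }
  structure(list(name = name, kind = kind, dist = dist,
                 params = params, levels = levels),
            class = "pr_attr_column")
}

#' @rdname attribute_schema
#' @export
default_attribute_schema <- function() {
  list(
    attribute_schema("ord1", "ordinal", "uniform", levels = 10L),
    attribute_schema("cat1", "categorical", "exponential", levels = 4L),
    attribute_schema("num1", "continuous", "normal"),
    attribute_schema("num2", "continuous", "lognormal")
  )
}

draw_latent <- function(n, dist, params) {
  p <- function(nm, default) if (!is.null(params[[nm]])) params[[nm]] else default
  switch(dist,
    normal      = stats::rnorm(n, p("mean", 0), p("sd", 1)),
    uniform     = stats::runif(n, p("min", 0), p("max", 1)),
    lognormal   = stats::rlnorm(n, p("meanlog", 0), p("sdlog", 1)),
    exponential = stats::rexp(n, p("rate", 1))
  )
}

#' Generate synthetic vertex attributes
#'
#' Draws an `n`-row attribute table from a schema (default:
#' [default_attribute_schema()]). Reproducible under `seed`.
#'
#' @param n number of vertices.
#' @param schema list of [attribute_schema()] columns.
#' @param seed optional integer seed.
#' @return A data frame with one column per schema entry. Ordinal columns
#'   are integers, categorical columns are factors, continuous columns are
#'   numeric.
#' @examples
#' synth_attributes(10, seed = 1)
#' @export
synth_attributes <- function(n, schema = default_attribute_schema(), seed = NULL) {
  if (length(n) != 1L || n < 1 || n != floor(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cols <- lapply(schema, function(col) {
    stopifnot(inherits(col, "pr_attr_column"))
    x <- draw_latent(n, col$dist, col$params)
    if (any(!is.finite(x))) stop("invalid distribution parameters", call. = FALSE)
    switch(col$kind,
      continuous = x,
      # ceiling of the scaled rank: monotone in the latent draw
      ordinal = as.integer(ceiling(col$levels * rank(x, ties.method = "first") / n)),
      categorical = factor(
        paste0("c", ceiling(col$levels * rank(x, ties.method = "first") / n)),
        levels = paste0("c", seq_len(col$levels))
      )
    )
  })
  names(cols) <- vapply(schema, `[[`, character(1), "name")
  as.data.frame(cols, stringsAsFactors = FALSE)
}
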