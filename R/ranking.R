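#' Harmonic numbers
#'
#' `harmonic()` returns the exact partial sum \eqn{H_n = \sum_{k=1}^n 1/k};
#' `harmonic_approx()` returns Euler's approximation
#' \eqn{H_n \approx \ln(n) + 1/(2n) + \gamma} with
#' \eqn{\gamma = 0.57722} (Euler-Mascheroni constant).
#'
#' @param n positive integer.
#' @return A single numeric value.
#' @examples
#' harmonic(4)          # 25/12
#' harmonic_approx(100) # within 1e-4 of harmonic(100)
#' @export
harmonic <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != floor(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  sum(1 / seq_len(n))
}

#' @rdname harmonic
#' @export
harmonic_approx <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != floor(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  log(n) + 1 / (2 * n) + 0.57722
}

#' Competition ranking of candidate distances
#'
#' Assigns each candidate its competition rank ("1224" style with minimum
#' rank for ties): the position of a candidate is 1 plus the number of
#' candidates at strictly smaller distance. Tied candidates share a
#' position and the following positions are skipped, so the ranking may
#' contain gaps (e.g. distances `c(15, 15, 20, 30)` rank as `1, 1, 3, 4`).
#'
#' @param distances numeric vector of nonnegative, finite distances.
#' @return Integer vector of positive ranks, aligned with the input.
#' @examples
#' competition_positions(c(15, 15, 20, 30)) # 1 1 3 4
#' competition_positions(c(5, 10, 15, 20))  # 1 2 3 4
#' @export
competition_positions <- function(distances) {
  if (length(distances) == 0L) {
    stop("`distances` must be non-empty", call. = FALSE)
  }
  if (!is.numeric(distances) || any(!is.finite(distances)) || any(distances < 0)) {
    stop("`distances` must be finite, nonnegative numbers", call. = FALSE)
  }
  as.integer(rank(distances, ties.method = "min"))
}

#' Rank-based selection probabilities
#'
#' Converts a vector of competition-rank positions into the priority
#' attachment probability mass function: the candidate at position \eqn{i}
#' is selected with probability proportional to \eqn{1/i}, normalized by
#' the generalized harmonic sum over the realized positions (each tied
#' candidate contributes its own \eqn{1/i} term). For positions
#' \eqn{1, \dots, m} this reduces to \eqn{P(i) = 1/(H_m \, i)} with
#' \eqn{H_m} the m-th harmonic number.
#'
#' @param positions integer vector of positive competition ranks.
#' @return An object of class `pr_pmf`: a list with `positions`,
#'   `probabilities` (summing to 1) and `normalizer` (the generalized
#'   harmonic sum).
#' @examples
#' selection_pmf(1:4)$probabilities        # 0.48 0.24 0.16 0.12
#' selection_pmf(c(1, 1, 3, 4))$normalizer # 31/12
#' @export
selection_pmf <- function(positions) {
  if (length(positions) == 0L) {
    stop("`positions` must be non-empty", call. = FALSE)
  }
  if (!is.numeric(positions) || any(!is.finite(positions)) ||
      any(positions < 1) || any(positions != floor(positions))) {
    stop("`positions` must be positive integers", call. = FALSE)
  }
  w <- 1 / positions
  normalizer <- sum(w)
  structure(
    list(
      positions = as.integer(positions),
      probabilities = w / normalizer,
      normalizer = normalizer
    ),
    class = "pr_pmf"
  )
}

#' @export
print.pr_pmf <- function(x, ...) {
  cat("Priority attachment selection PMF (", length(x$positions),
      " candidates, normalizer ", format(x$normalizer), ")\n", sep = "")
  print(data.frame(position = x$positions,
                   probability = x$probabilities,
                   percent = round(100 * x$probabilities)))
  invisible(x)
}

#' Sample edge targets without replacement
#'
#' Draws `k` distinct candidates according to a rank-based selection PMF.
#' After each draw the drawn candidate is removed and the remaining
#' probabilities are renormalized proportionally (successive sampling),
#' which is exactly the semantics of [sample()] with a `prob` argument.
#'
#' @param pmf a `pr_pmf` from [selection_pmf()].
#' @param k number of targets to draw; at most the number of candidates.
#' @param candidates optional vector of candidate identifiers aligned with
#'   the PMF; defaults to candidate indices `1:m`.
#' @return Vector of `k` distinct candidate identifiers, in draw order.
#' @export
sample_targets <- function(pmf, k, candidates = seq_along(pmf$probabilities)) {
  stopifnot(inherits(pmf, "pr_pmf"))
  m <- length(pmf$probabilities)
  if (length(candidates) != m) {
    stop("`candidates` must align with the PMF", call. = FALSE)
  }
  if (length(k) != 1L || k < 1 || k != floor(k)) {
    stop("`k` must be a single positive integer", call. = FALSE)
  }
  if (k > m) {
    stop("`k` exceeds the number of candidates", call. = FALSE)
  }
  if (m == 1L) return(candidates)
  # sample() draws sequentially without replacement, renormalizing the
  # remaining weights after each draw
  idx <- sample.int(m, size = k, replace = FALSE, prob = pmf$probabilities)
  candidates[idx]
}
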