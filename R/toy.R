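#' The worked five-person toy example
#'
#' `toy_network_attrs()` returns the five-person attribute table (Alice 30
#' F, Bob 40 M, Cecil 25 M, Diane 20 F, Eve 35 F). `toy_rankings()` works
#' the whole priority-attachment example: for every person it evaluates the
#' age/sex social distance (absolute age difference, plus 10 when the sexes
#' differ), ranks the other four by competition ranking, and converts the
#' ranking into selection probabilities. Alice's row comes out as exactly
#' 12/25, 6/25, 4/25, 3/25 (48/24/16/12 percent); Bob's tied top pair at
#' 12/31 each (38.71%, printing as 39%); Cecil's three-way tie at 4/13
#' (30.77%, printing as 31%).
#'
#' @return `toy_network_attrs()`: a data frame. `toy_rankings()`: a named
#'   list, one data frame per person, with columns `name`, `dist`, `rank`,
#'   `prob`, `percent`.
#' @examples
#' toy_rankings()$Alice
#' @export
toy_network_attrs <- function() {
  data.frame(
    name = c("Alice", "Bob", "Cecil", "Diane", "Eve"),
    age = c(30, 40, 25, 20, 35),
    sex = factor(c("female", "male", "male", "female", "female"))
  )
}

#' @rdname toy_network_attrs
#' @export
toy_rankings <- function() {
  attrs <- toy_network_attrs()
  g <- pr_graph(nrow(attrs), attrs = attrs, directed = TRUE)
  spec <- distance_spec("toy_age_sex")
  out <- lapply(seq_len(nrow(attrs)), function(v) {
    cand <- setdiff(seq_len(nrow(attrs)), v)
    d <- evaluate_distance(spec, g, v, cand)
    pos <- competition_positions(d)
    pmf <- selection_pmf(pos)
    ord <- order(pos, attrs$name[cand])
    data.frame(
      name = attrs$name[cand][ord],
      dist = d[ord],
      rank = pos[ord],
      prob = pmf$probabilities[ord],
      percent = round(100 * pmf$probabilities[ord])
    )
  })
  names(out) <- attrs$name
  out
}
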