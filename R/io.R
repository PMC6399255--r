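#' Read and write networks
#'
#' `read_network()` reads a whitespace-separated edge list (`#` comments
#' allowed; arbitrary vertex labels are mapped to contiguous 1-based ids,
#' with the mapping kept in the `name` vertex attribute) or a GraphML file
#' (vertex attributes become attribute-table columns). Duplicate edges are
#' collapsed with a warning. `write_network()` writes either format; edge
#' lists are written as 0-based `src<TAB>dst` rows. A JSON sidecar with the
#' provenance fields in `config` is written next to the output when
#' supplied.
#'
#' @param path file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @param directed edge semantics for edge-list input.
#' @param g an igraph object.
#' @param config optional named list echoed into `<path>.json`.
#' @return `read_network()` returns an igraph object; `write_network()`
#'   returns `path` invisibly.
#' @export
read_network <- function(path, format = c("edgelist", "graphml"),
                         directed = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    stop("edge list parse failure at line ", bad[1], call. = FALSE)
  }
  ends <- cbind(vapply(parts, `[[`, character(1), 1),
                vapply(parts, `[[`, character(1), 2))
  labels <- unique(as.vector(t(ends)))
  el <- matrix(match(ends, labels), ncol = 2)
  if (anyDuplicated(el)) {
    warning("duplicate edges collapsed", call. = FALSE)
    el <- unique(el)
  }
  g <- pr_graph(length(labels), directed = directed, edges = el)
  igraph::set_vertex_attr(g, "name", value = labels)
}

#' @rdname read_network
#' @export
write_network <- function(g, path, format = c("edgelist", "graphml"),
                          config = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g, names = FALSE) - 1L
    utils::write.table(el, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  if (!is.null(config)) {
    jsonlite::write_json(config, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a vertex attribute table
#'
#' CSV with a header; string columns become factors so that categorical
#' kernels and the naive-Bayes distance treat them as labels.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_attributes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = TRUE)
}
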