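#' Attributed graph construction and accessors
#'
#' The package represents networks as igraph objects whose vertices carry a
#' typed attribute table. `pr_graph()` builds an empty (or edge-list
#' initialized) attributed graph; `vertex_attributes()` extracts the
#' attribute table as a data frame with one row per vertex.
#'
#' @param n number of vertices; ignored when `edges` carries larger ids.
#' @param attrs optional data frame of vertex attributes (`n` rows).
#' @param directed logical; directed edge semantics.
#' @param edges optional 2-column matrix of 1-based vertex ids.
#' @return An igraph object.
#' @export
pr_graph <- function(n, attrs = NULL, directed = TRUE, edges = NULL) {
  g <- igraph::make_empty_graph(n = n, directed = directed)
  if (!is.null(edges) && NROW(edges) > 0) {
    g <- igraph::add_edges(g, t(as.matrix(edges)))
  }
  if (!is.null(attrs)) {
    if (nrow(attrs) != n) {
      stop("attribute table must have one row per vertex", call. = FALSE)
    }
    for (col in names(attrs)) {
      g <- igraph::set_vertex_attr(g, col, value = attrs[[col]])
    }
  }
  g
}

#' @rdname pr_graph
#' @param g an igraph object.
#' @export
vertex_attributes <- function(g) {
  cols <- setdiff(igraph::vertex_attr_names(g), "name")
  out <- as.data.frame(lapply(cols, function(a) igraph::vertex_attr(g, a)),
                       col.names = cols, stringsAsFactors = FALSE)
  if (length(cols) == 0L) {
    out <- data.frame(row.names = seq_len(igraph::vcount(g)))
  }
  out
}

#' Simplify a directed network to an undirected simple graph
#'
#' Merges reciprocal edges, drops edge direction, and removes any duplicate
#' edges or self-loops. Idempotent; undirected inputs are only
#' de-duplicated.
#'
#' @param g an igraph object.
#' @return An undirected simple igraph object with the same vertices and
#'   attributes.
#' @export
simplify_network <- function(g) {
  igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
}
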