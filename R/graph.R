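#' Undirected graph structures over variables
#'
#' A `graph_structure` is the support set of a Gaussian graphical model: a
#' simple undirected graph over `p` variables whose edges mark the variable
#' pairs allowed a nonzero precision (hence a direct conditional association).
#' Edges are stored as a two-column integer matrix with `i < j`, sorted
#' lexicographically, with no self-loops or duplicates.
#'
#' @param p number of nodes (variables), at least 1.
#' @param edges two-column matrix (or data frame) of node index pairs; `NULL`
#'   or zero rows gives the empty graph.
#' @return an object of class `graph_structure` with fields `p` and `edges`.
#' @examples
#' g <- graph_structure(3, rbind(c(1, 2), c(2, 3)))
#' n_edges(g)
#' @export
graph_structure <- function(p, edges = NULL) {
  p <- as.integer(p)
  if (length(p) != 1L || is.na(p) || p < 1L) {
    ggmnet_abort("bad_graph", "`p` must be a single positive integer")
  }
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "integer"
    if (ncol(edges) != 2L) ggmnet_abort("bad_graph", "`edges` needs two columns")
    if (anyNA(edges) || any(edges < 1L) || any(edges > p)) {
      ggmnet_abort("bad_graph", "edge indices must lie in 1..p")
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      ggmnet_abort("bad_graph", "self-loops are not allowed")
    }
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  colnames(edges) <- c("i", "j")
  structure(list(p = p, edges = edges), class = "graph_structure")
}

#' @export
print.graph_structure <- function(x, ...) {
  cat(sprintf("<graph_structure: %d nodes, %d edges>\n", x$p, n_edges(x)))
  invisible(x)
}

#' Number of edges of a graph structure
#' @param graph a `graph_structure`.
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' @rdname graph_structure
#' @export
empty_graph <- function(p) graph_structure(p)

#' @rdname graph_structure
#' @export
complete_graph <- function(p) {
  graph_structure(p, t(utils::combn(p, 2L)))
}

#' Adjacency matrix of a graph structure
#' @param graph a `graph_structure`.
#' @return a `p x p` 0/1 integer matrix.
#' @export
as_adjacency <- function(graph) {
  stopifnot(inherits(graph, "graph_structure"))
  a <- matrix(0L, graph$p, graph$p)
  if (n_edges(graph) > 0L) {
    a[graph$edges] <- 1L
    a[graph$edges[, 2:1, drop = FALSE]] <- 1L
  }
  a
}

# inverse of as_adjacency
graph_from_adjacency01 <- function(adj) {
  p <- nrow(adj)
  idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  graph_structure(p, idx)
}
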