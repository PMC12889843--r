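#' Labeled binary functional-connectivity graph
#'
#' A `functional_graph` is an undirected, unweighted graph over a fixed,
#' ordered set of neurons, typically produced by thresholding a pairwise
#' correlation matrix for one behavioral stage. Node identity matters:
#' cross-stage comparisons (spectral distance) require the three stage
#' graphs of a session to share the same node set in the same order.
#'
#' @param adjacency square binary matrix, symmetric with zero diagonal.
#' @param node_ids optional character vector of neuron labels; defaults to
#'   the matrix dimnames or `"n1" ... "nN"`.
#' @param stage optional stage label (`"H"`, `"SB"`, `"SN"` or other).
#' @param threshold correlation threshold used to build the graph, if any.
#' @return An object of class `functional_graph` with elements `adjacency`,
#'   `node_ids`, `stage`, `threshold`.
#' @export
functional_graph <- function(adjacency, node_ids = NULL, stage = NA_character_,
                             threshold = NA_real_) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  check_adjacency(adjacency)
  n <- nrow(adjacency)
  if (is.null(node_ids)) {
    node_ids <- rownames(adjacency) %||% paste0("n", seq_len(n))
  }
  if (length(node_ids) != n) stopf("node_ids must have length %d", n)
  dimnames(adjacency) <- list(node_ids, node_ids)
  structure(
    list(adjacency = adjacency, node_ids = as.character(node_ids),
         stage = stage, threshold = threshold),
    class = "functional_graph"
  )
}

#' @export
print.functional_graph <- function(x, ...) {
  cat(sprintf("<functional_graph> %d nodes, %d edges%s%s\n",
              n_nodes(x), n_edges(x),
              if (is.na(x$stage)) "" else paste0(", stage ", x$stage),
              if (is.na(x$threshold)) "" else
                sprintf(", threshold %.3g", x$threshold)))
  invisible(x)
}

## Accept either a functional_graph or a bare adjacency matrix.
as_adjacency <- function(g) {
  if (inherits(g, "functional_graph")) return(g$adjacency)
  g <- as.matrix(g)
  storage.mode(g) <- "double"
  check_adjacency(g)
  g
}

#' Node and edge counts
#' @param g a `functional_graph` or adjacency matrix.
#' @return Integer count.
#' @export
n_nodes <- function(g) nrow(as_adjacency(g))

#' @rdname n_nodes
#' @export
n_edges <- function(g) as.integer(sum(as_adjacency(g)) / 2)

#' Node degrees
#' @param g a `functional_graph` or adjacency matrix.
#' @return Numeric vector of degrees, named by node.
#' @export
degrees <- function(g) rowSums(as_adjacency(g))
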