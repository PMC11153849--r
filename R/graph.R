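#' Neighborhood structure of a heterogeneous network
#'
#' Derives the graph the encoder operates on from the dense network matrix:
#' an edge joins `i` and `j` whenever `Y[i, j] > threshold`, and every node
#' carries an enforced self-loop. Two views are kept: `adj`, the logical
#' adjacency *without* self-loops (used by the feature convolution, whose
#' self term enters separately), and `mask`, the adjacency *with* self-loops
#' (the support of the attention softmax).
#'
#' @param Y square numeric matrix (a `"hetnet"` object is also accepted).
#' @param threshold edge threshold tau; default 0 keeps every nonzero entry.
#' @return Object of class `"lcat_graph"`: list with `adj`, `mask`, `deg`
#'   (neighbor counts excluding self), `nbrs` (list of neighbor indices
#'   including self, ascending), and `n`.
#' @export
graph_neighborhoods <- function(Y, threshold = 0) {
  if (inherits(Y, "hetnet")) Y <- Y$Y
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == ncol(Y))
  adj <- Y > threshold
  diag(adj) <- FALSE
  mask <- adj
  diag(mask) <- TRUE
  structure(list(adj = adj, mask = mask, deg = rowSums(adj),
                 nbrs = apply(mask, 1L, which, simplify = FALSE),
                 n = nrow(Y)),
            class = "lcat_graph")
}

#' @export
print.lcat_graph <- function(x, ...) {
  cat(sprintf("Graph: %d nodes, %d undirected edges (self-loops enforced)\n",
              x$n, sum(x$adj) / 2))
  invisible(x)
}
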