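#' Construct a weighted directed acyclic graph
#'
#' The causal structures handled by this package are linear-Gaussian
#' DAGs: each edge carries a standardized path coefficient and each node
#' a residual standard deviation.  The constructor validates acyclicity
#' (a topological order must exist), that every weight belongs to an
#' edge, and that residual standard deviations are strictly positive.
#'
#' @param nodes character vector of node labels (order is kept).
#' @param edges two-column matrix or data frame of `(parent, child)`
#'   labels; may have zero rows.
#' @param weights numeric vector of path coefficients, one per edge row.
#' @param noise_sd named numeric vector of residual standard deviations;
#'   defaults to 1 for every node.
#' @return an object of class `weighted_dag`.
#' @examples
#' weighted_dag(c("a", "b", "c"),
#'              rbind(c("a", "b"), c("b", "c")), weights = c(0.5, 0.5))
#' @export
weighted_dag <- function(nodes, edges = NULL, weights = numeric(0),
                         noise_sd = NULL) {
  stopifnot(is.character(nodes), length(nodes) >= 1, !anyDuplicated(nodes))
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    stopifnot(ncol(edges) == 2)
    storage.mode(edges) <- "character"
  }
  colnames(edges) <- c("parent", "child")
  if (length(weights) != nrow(edges))
    stop("need exactly one weight per edge")
  if (!all(c(edges) %in% nodes)) stop("edge endpoints must be listed nodes")
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  if (anyDuplicated(paste(edges[, 1], edges[, 2])))
    stop("duplicated edges")
  if (is.null(noise_sd)) noise_sd <- stats::setNames(rep(1, length(nodes)), nodes)
  if (is.null(names(noise_sd))) names(noise_sd) <- nodes
  if (!all(nodes %in% names(noise_sd)) || any(noise_sd <= 0))
    stop("noise_sd must be strictly positive for every node")
  dag <- structure(list(nodes = nodes, edges = edges,
                        weights = as.numeric(weights),
                        noise_sd = noise_sd[nodes]),
                   class = "weighted_dag")
  if (is.null(topological_order(dag))) stop("edge set contains a directed cycle")
  dag
}

#' Topological order of a DAG
#'
#' @param dag a [weighted_dag] or a square adjacency matrix.
#' @return integer vector of node indices in topological order, or
#'   `NULL` if the graph is cyclic.
#' @export
topological_order <- function(dag) {
  A <- if (inherits(dag, "weighted_dag")) adjacency_matrix(dag) else dag != 0
  p <- nrow(A)
  indeg <- colSums(A)
  order <- integer(0)
  avail <- which(indeg == 0)
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    ch <- which(A[v, ] != 0)
    indeg[ch] <- indeg[ch] - 1
    avail <- sort(c(avail, ch[indeg[ch] == 0 & !(ch %in% order)]))
  }
  if (length(order) < p) NULL else order
}

#' Boolean adjacency matrix of a weighted DAG
#' @param dag a [weighted_dag].
#' @return logical p x p matrix, `[parent, child]`.
#' @export
adjacency_matrix <- function(dag) {
  p <- length(dag$nodes)
  A <- matrix(FALSE, p, p, dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$edges))
    A[cbind(dag$edges[, 1], dag$edges[, 2])] <- TRUE
  A
}

#' Path-coefficient matrix of a weighted DAG
#' @param dag a [weighted_dag].
#' @return numeric p x p matrix `W` with `W[parent, child]` the path
#'   coefficient and zeros elsewhere.
#' @export
coef_matrix <- function(dag) {
  p <- length(dag$nodes)
  W <- matrix(0, p, p, dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$edges))
    W[cbind(dag$edges[, 1], dag$edges[, 2])] <- dag$weights
  W
}

#' @export
print.weighted_dag <- function(x, ...) {
  cat(sprintf("<weighted_dag> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    for (k in seq_len(min(10, nrow(x$edges))))
      cat(sprintf("  %s -> %s  (%.3f)\n",
                  x$edges[k, 1], x$edges[k, 2], x$weights[k]))
    if (nrow(x$edges) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' True total causal effect in a linear-Gaussian DAG
#'
#' The total effect of `x` on `y` is the sum over all directed paths
#' from `x` to `y` of the products of path coefficients, equal to the
#' `(x, y)` entry of `(I - W)^-1 - I` for coefficient matrix `W`.
#'
#' @param dag a [weighted_dag].
#' @param x,y node labels (source and target).
#' @return the total effect (0 when no directed path exists).
#' @examples
#' d <- weighted_dag(c("a", "b", "c"),
#'                   rbind(c("a", "b"), c("b", "c")), c(0.5, 0.5))
#' true_total_effect(d, "a", "c")  # 0.25
#' @export
true_total_effect <- function(dag, x, y) {
  stopifnot(inherits(dag, "weighted_dag"))
  if (!(x %in% dag$nodes) || !(y %in% dag$nodes))
    stop("unknown node label")
  W <- coef_matrix(dag)
  Tm <- solve(diag(nrow(W)) - W) - diag(nrow(W))
  dimnames(Tm) <- dimnames(W)
  Tm[x, y]
}

# independent oracle: exhaustive directed-path enumeration
total_effect_by_paths <- function(dag, x, y) {
  W <- coef_matrix(dag)
  labels <- dag$nodes
  xi <- match(x, labels); yi <- match(y, labels)
  total <- 0
  recurse <- function(v, prod) {
    ch <- which(W[v, ] != 0)
    for (u in ch) {
      w <- prod * W[v, u]
      if (u == yi) total <<- total + w
      else recurse(u, w)
    }
  }
  recurse(xi, 1)
  total
}
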