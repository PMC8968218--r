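#' Maximum-likelihood GGM fit under a fixed edge structure
#'
#' Computes the maximum-likelihood concentration matrix `K` subject to
#' zero constraints on non-edges, by node-wise regressions iterated to
#' convergence (the classical covariance-selection algorithm).  At the
#' solution `(K^-1)[i,j] = S[i,j]` for all edges and the diagonal, and
#' `K[i,j]` is exactly zero off-structure.
#'
#' @param S positive-definite sample correlation (or covariance) matrix.
#' @param adjacency symmetric hollow 0/1 (or logical) matrix of edges.
#' @param tol convergence tolerance on the implied covariances.
#' @param maxit iteration cap; non-convergence raises an error carrying
#'   the residual norm.
#' @return the concentration matrix `K`.
#' @export
fit_ggm_given_structure <- function(S, adjacency, tol = 1e-12, maxit = 5000) {
  S <- as.matrix(S)
  adjacency <- matrix(as.integer(adjacency != 0), nrow(S), ncol(S))
  if (!isSymmetric(unname(S))) stop("S must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency must be hollow")
  if (!isSymmetric(adjacency)) stop("adjacency must be symmetric")
  fit <- cpp_ggm_fit(S, adjacency, tol, maxit)
  if (!fit$converged || fit$resid > 1e-6)
    stop(sprintf("constrained GGM fit did not converge (residual %.3g)",
                 fit$resid))
  K <- fit$K
  dimnames(K) <- dimnames(S)
  K
}

#' Extended BIC for a Gaussian graphical model
#'
#' `score = -2 loglik + E log n + 4 E gamma log p`; lower is better.
#' `gamma = 0` reduces to the ordinary BIC penalty.
#'
#' @param loglik model log-likelihood.
#' @param n_edges number of edges `E`.
#' @param n sample size.
#' @param p number of nodes.
#' @param gamma EBIC hyperparameter.
#' @return the EBIC score.
#' @export
ebic_score <- function(loglik, n_edges, n, p, gamma = 0.5) {
  stopifnot(n > 0)
  -2 * loglik + n_edges * log(n) + 4 * gamma * n_edges * log(p)
}

# profile log-likelihood used for EBIC, up to constants
ggm_loglik <- function(S, K, n) {
  n / 2 * (determinant(K, logarithm = TRUE)$modulus[1] - sum(S * K))
}

#' Estimate a partial-correlation network by stepwise EBIC selection
#'
#' The unregularized model-selection procedure used for large samples:
#' (1) a graphical-lasso path (100 log-spaced penalties by default)
#' proposes candidate sparsity patterns; (2) each pattern is refitted
#' without penalty and scored by [ebic_score]; (3) from the best
#' candidate, a best-first stepwise search evaluates every single-edge
#' addition or removal (refit + EBIC) and takes the best strictly
#' improving move until none improves.  Edge weights of the selected
#' model are partial correlations `-K[i,j]/sqrt(K[i,i] K[j,j])`.
#'
#' @param S sample correlation matrix (a covariance matrix is converted
#'   with a warning: the pipeline gaussianizes to unit variance upstream).
#' @param n sample size behind `S`.
#' @param gamma EBIC hyperparameter (default 0.5, the customary default).
#' @param nlambda number of penalties on the candidate path.
#' @param lambda_min_ratio smallest penalty as a fraction of the largest
#'   absolute off-diagonal entry of `S`.
#' @param labels node labels (defaults to the column names of `S`).
#' @return an object of class `pcnet`: a list with `labels`, `weights`
#'   (partial-correlation matrix, zero diagonal), `edges` (data frame
#'   `node1,node2,weight`), `K`, `adjacency`, `ebic`, `ebic_trace`,
#'   `gamma`, and `n`.
#' @export
ggm_model_select <- function(S, n, gamma = 0.5, nlambda = 100,
                             lambda_min_ratio = 0.01, labels = NULL) {
  S <- as.matrix(S)
  p <- nrow(S)
  if (is.null(labels)) labels <- colnames(S) %||% paste0("x", seq_len(p))
  if (max(abs(diag(S) - 1)) > 1e-8) {
    warning("S does not look like a correlation matrix; converting with cov2cor")
    S <- stats::cov2cor(S)
  }
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("S must be positive definite")
  lam_max <- max(abs(S[upper.tri(S)]), 1e-4)
  lambdas <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                     length.out = nlambda))
  sel <- cpp_ggm_select(S, n, gamma, lambdas)
  W <- sel$pcor
  dimnames(W) <- list(labels, labels)
  idx <- which(upper.tri(W) & sel$adjacency == 1, arr.ind = TRUE)
  edges <- data.frame(node1 = labels[idx[, 1]], node2 = labels[idx[, 2]],
                      weight = W[idx], stringsAsFactors = FALSE)
  structure(list(labels = labels, weights = W,
                 edges = edges[order(edges$node1, edges$node2), ,
                               drop = FALSE],
                 K = sel$K, adjacency = sel$adjacency == 1,
                 ebic = sel$ebic, ebic_trace = sel$ebic_trace,
                 gamma = gamma, n = n),
            class = "pcnet")
}

#' @export
print.pcnet <- function(x, ...) {
  cat(sprintf("<pcnet> %d nodes, %d edges, EBIC %.2f (gamma = %.2f, n = %d)\n",
              length(x$labels), nrow(x$edges), x$ebic, x$gamma, x$n))
  invisible(x)
}

pcnet_igraph <- function(net, absolute = FALSE) {
  w <- net$edges$weight
  igraph::graph_from_data_frame(
    cbind(net$edges[, c("node1", "node2")],
          weight = if (absolute) abs(w) else w),
    directed = FALSE,
    vertices = data.frame(name = net$labels))
}

#' Centrality indices of a partial-correlation network
#'
#' Strength is the sum of absolute edge weights at a node.  Distance-
#' based measures use edge lengths `1/|weight|`: closeness is the
#' inverse of the summed shortest-path distances to all other nodes,
#' and betweenness counts appearances on all-pairs shortest paths
#' (endpoints excluded, ties split equally).  On a disconnected network
#' closeness is computed within components and the result is flagged.
#'
#' @param net a `pcnet`.
#' @return a data frame with columns `node`, `strength`, `closeness`,
#'   `betweenness`, and attribute `disconnected`.
#' @export
centrality <- function(net) {
  stopifnot(inherits(net, "pcnet"))
  strength <- rowSums(abs(net$weights))
  g <- pcnet_igraph(net, absolute = TRUE)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$weight <- 1 / igraph::E(g)$weight  # lengths
  comp <- igraph::components(g)
  disconnected <- comp$no > 1
  closeness <- numeric(length(net$labels))
  names(closeness) <- net$labels
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    if (length(members) == 1) { closeness[members] <- 0; next }
    sub <- igraph::induced_subgraph(g, members)
    d <- igraph::distances(sub)
    closeness[members] <- 1 / rowSums(d)
  }
  btw <- igraph::betweenness(g, directed = FALSE)
  data.frame(node = net$labels, strength = unname(strength),
             closeness = unname(closeness[net$labels]),
             betweenness = unname(btw[net$labels]),
             row.names = NULL) -> out
  attr(out, "disconnected") <- disconnected
  out
}

#' Write a network's standard artifacts
#'
#' Emits the square weight matrix (CSV), the long edge list (CSV), and
#' GraphML and DOT renderings of the weighted graph.
#'
#' @param net a `pcnet`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of written paths.
#' @export
write_network <- function(net, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_matrix.csv", "_edges.csv",
                                           ".graphml", ".dot")))
  write.csv(data.frame(node = net$labels, net$weights,
                       check.names = FALSE),
            paths[1], row.names = FALSE)
  write.csv(net$edges, paths[2], row.names = FALSE)
  g <- pcnet_igraph(net)
  igraph::write_graph(g, paths[3], format = "graphml")
  igraph::write_graph(g, paths[4], format = "dot")
  paths
}
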