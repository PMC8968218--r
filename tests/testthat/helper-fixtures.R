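# Shared fixtures: known sparse GGMs, multivariate-normal sampling,
# hand-built DAG sample sets, and brute-force graph oracles.

# sparse precision matrix with |partial correlation| in [rmin, rmax]
make_sparse_ggm <- function(p, n_edges, rmin, rmax, seed) {
  set.seed(seed)
  repeat {
    K <- diag(p)
    pairs <- which(upper.tri(K), arr.ind = TRUE)
    es <- pairs[sample(nrow(pairs), n_edges), , drop = FALSE]
    v <- sample(c(-1, 1), n_edges, TRUE) * runif(n_edges, rmin, rmax)
    for (k in seq_len(n_edges))
      K[es[k, 1], es[k, 2]] <- K[es[k, 2], es[k, 1]] <- -v[k]
    if (min(eigen(K, TRUE, only.values = TRUE)$values) > 0.05) {
      pc <- -stats::cov2cor(K); diag(pc) <- 0
      if (min(abs(pc[pc != 0])) >= rmin * 0.99)
        return(list(K = K, adj = pc != 0, pcor = pc,
                    Sigma = stats::cov2cor(solve(K))))
    }
  }
}

rmvn <- function(n, Sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(rnorm(n * ncol(Sigma)), n) %*% chol(Sigma)
  colnames(z) <- colnames(Sigma) %||% paste0("x", seq_len(ncol(Sigma)))
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a dag_sample_set from an explicit list of edge lists, each a
# 2-column matrix of (parent, child) labels
make_sample_set <- function(edge_lists, labels) {
  p <- length(labels)
  masks <- matrix(0L, length(edge_lists), p)
  colnames(masks) <- labels
  for (r in seq_along(edge_lists)) {
    el <- edge_lists[[r]]
    if (is.null(el) || NROW(el) == 0) next
    el <- matrix(el, ncol = 2)
    for (k in seq_len(nrow(el))) {
      i <- match(el[k, 1], labels); j <- match(el[k, 2], labels)
      masks[r, j] <- bitwOr(masks[r, j], bitwShiftL(1L, i - 1L))
    }
  }
  structure(list(parent_masks = masks, labels = labels, p = p,
                 iterations = length(edge_lists), burn_in = 0,
                 thinning = 1, seed = NA, sampler = "fixture",
                 score_trace = numeric(length(edge_lists)),
                 acceptance_rate = NA_real_, am = 1, aw = p + 2,
                 edge_logprior = 0),
            class = "dag_sample_set")
}

# brute-force betweenness on a weighted undirected network: distances
# 1/|w|, all shortest paths enumerated via Floyd-Warshall path counts
brute_betweenness <- function(W, eps = 1e-12) {
  p <- nrow(W)
  D <- 1 / abs(W); D[W == 0] <- Inf; diag(D) <- 0
  cnt <- matrix(0, p, p); cnt[W != 0] <- 1
  for (k in seq_len(p)) for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j || i == k || j == k) next
    alt <- D[i, k] + D[k, j]
    if (alt < D[i, j] - eps) { D[i, j] <- alt; cnt[i, j] <- cnt[i, k] * cnt[k, j] }
    else if (is.finite(alt) && abs(alt - D[i, j]) <= eps)
      cnt[i, j] <- cnt[i, j] + cnt[i, k] * cnt[k, j]
  }
  btw <- numeric(p)
  for (v in seq_len(p)) for (s in seq_len(p - 1)) for (t in (s + 1):p) {
    if (s == v || t == v || !is.finite(D[s, t])) next
    through <- if (abs(D[s, v] + D[v, t] - D[s, t]) <= eps)
      cnt[s, v] * cnt[v, t] else 0
    if (through > 0) btw[v] <- btw[v] + through / cnt[s, t]
  }
  btw
}

# total DAG score from an adjacency matrix, via the score-table cache
score_dag_total <- function(tb, A) {
  s <- 0
  for (j in seq_len(ncol(A)))
    s <- s + local_score(j, which(A[, j] != 0), tb)
  s
}

# identifiable 6-node DAG (every edge compelled by unshielded colliders
# and orientation propagation), unit marginal variances
identifiable_dag6 <- function() {
  unit_variance_noise(weighted_dag(
    paste0("x", 1:6),
    rbind(c("x1", "x3"), c("x2", "x3"), c("x3", "x4"),
          c("x3", "x5"), c("x4", "x6"), c("x5", "x6")),
    c(0.6, 0.5, 0.55, -0.5, 0.6, 0.45)))
}

# the p=8 GGM used for bootstrap calibration: two edges share weight 0.30
boot_calibration_ggm <- function() {
  K <- diag(8)
  set_e <- function(K, i, j, r) { K[i, j] <- K[j, i] <- -r; K }
  K <- set_e(K, 1, 2, 0.30); K <- set_e(K, 3, 4, 0.30)
  K <- set_e(K, 1, 5, 0.25); K <- set_e(K, 2, 6, -0.25)
  K <- set_e(K, 5, 7, 0.35); K <- set_e(K, 6, 8, 0.20)
  K <- set_e(K, 4, 7, -0.25)
  pc <- -stats::cov2cor(K); diag(pc) <- 0
  list(K = K, pcor = pc, Sigma = stats::cov2cor(solve(K)))
}
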