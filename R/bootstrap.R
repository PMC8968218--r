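#' Bootstrap resampling indices
#'
#' The resampling plan depends only on `(seed, B, n)`, never on the
#' estimator, so replicated analyses can replay identical indices.
#'
#' @param n sample size.
#' @param B number of replicates.
#' @param seed integer seed.
#' @return integer `B x n` matrix of row indices.
#' @export
boot_indices <- function(n, B, seed) {
  with_seed(seed, matrix(sample.int(n, n * B, replace = TRUE), nrow = B))
}

# lean selection path used inside resampling loops: same procedure as
# ggm_model_select, returning only the vectorised upper triangle
select_pcor_vech <- function(S, n, gamma, nlambda, lambda_min_ratio) {
  lam_max <- max(abs(S[upper.tri(S)]), 1e-4)
  lambdas <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                     length.out = nlambda))
  sel <- cpp_ggm_select(S, n, gamma, lambdas)
  sel$pcor[upper.tri(sel$pcor)]
}

#' Non-parametric bootstrap of network edge weights
#'
#' Each replicate resamples the rows with replacement, re-runs
#' [ggm_model_select] with identical settings, and records the full
#' edge-weight vector (absent edges as exact 0).  Per-edge 95% quantile
#' intervals and inclusion frequencies summarise the draws.  Replicates
#' whose refit fails are dropped and counted; more than 1% failures
#' aborts.
#'
#' @param z gaussianized data matrix (rows = participants).
#' @param B number of bootstrap replicates (>= 100 for quantile CIs).
#' @param seed integer seed.
#' @param gamma,nlambda,lambda_min_ratio selection settings, as in
#'   [ggm_model_select].
#' @return an object of class `boot_result`: `B`, `edge_draws`
#'   (`B x p(p-1)/2`, columns named `a--b`), `estimate` (full-sample
#'   edge weights), `ci` (2.5% / 97.5% bounds), `inclusion_freq`,
#'   `labels`, `failures`, and the full-sample `net`.
#' @export
nonparametric_boot <- function(z, B = 500, seed = NULL, gamma = 0.5,
                               nlambda = 100, lambda_min_ratio = 0.01) {
  z <- as.matrix(z)
  if (B < 100) stop("B must be at least 100 for quantile intervals")
  n <- nrow(z)
  labels <- colnames(z) %||% paste0("x", seq_len(ncol(z)))
  colnames(z) <- labels
  net <- ggm_model_select(cor(z), n, gamma, nlambda, lambda_min_ratio, labels)
  ut <- upper.tri(net$weights)
  idx <- boot_indices(n, B, seed)
  draws <- matrix(NA_real_, B, sum(ut))
  colnames(draws) <- vech_names(labels)
  failures <- 0L
  for (b in seq_len(B)) {
    Sb <- cor(z[idx[b, ], , drop = FALSE])
    w <- tryCatch(select_pcor_vech(Sb, n, gamma, nlambda, lambda_min_ratio),
                  error = function(e) NULL)
    if (is.null(w)) { failures <- failures + 1L; next }
    draws[b, ] <- w
  }
  if (failures > 0.01 * B)
    stop(sprintf("%d of %d bootstrap replicates failed", failures, B))
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  ci <- t(apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  colnames(ci) <- c("lo", "hi")
  structure(list(B = nrow(draws), edge_draws = draws,
                 estimate = stats::setNames(net$weights[ut], colnames(draws)),
                 ci = ci, inclusion_freq = colMeans(draws != 0),
                 labels = labels, failures = failures, net = net,
                 seed = seed),
            class = "boot_result")
}

#' @export
print.boot_result <- function(x, ...) {
  cat(sprintf("<boot_result> %d replicates over %d edge slots (%d failures)\n",
              x$B, ncol(x$edge_draws), x$failures))
  invisible(x)
}

#' Bootstrap edge-difference test
#'
#' Two edges differ significantly when the 95% bootstrap quantile
#' interval of their weight difference excludes 0.
#'
#' @param result a `boot_result`.
#' @param edge_a,edge_b edge names (`a--b` as in the draw columns).
#' @return list with `significant` (flag) and the difference `interval`.
#' @export
edge_difference_test <- function(result, edge_a, edge_b) {
  stopifnot(inherits(result, "boot_result"))
  nm <- colnames(result$edge_draws)
  if (!(edge_a %in% nm) || !(edge_b %in% nm))
    stop("unknown edge id; see colnames(result$edge_draws)")
  d <- result$edge_draws[, edge_a] - result$edge_draws[, edge_b]
  qi <- quantile(d, c(0.025, 0.975), names = FALSE)
  list(significant = qi[1] > 0 || qi[2] < 0, interval = qi)
}

#' Edge-pair significance matrix
#'
#' Applies [edge_difference_test] to every pair of edges present in the
#' full-sample network; the result is symmetric in edge-pair exchange.
#'
#' @param result a `boot_result`.
#' @return logical matrix over the present edges.
#' @export
edge_difference_matrix <- function(result) {
  nm <- colnames(result$edge_draws)
  present <- nm[result$estimate != 0]
  m <- matrix(FALSE, length(present), length(present),
              dimnames = list(present, present))
  if (length(present) < 2) return(m)
  for (a in seq_along(present)) for (b in seq_along(present)) {
    if (a < b) {
      sig <- edge_difference_test(result, present[a], present[b])$significant
      m[a, b] <- sig; m[b, a] <- sig
    }
  }
  m
}

#' Case-dropping bootstrap of centrality stability
#'
#' At each drop fraction, centralities are recomputed on row subsamples
#' and correlated (Spearman by default) with the full-sample values.
#' The CS coefficient of a centrality index is the largest drop fraction
#' at which that correlation is at least 0.7 in at least 95% of
#' replicates, requiring every smaller probed fraction to qualify too.
#'
#' @param z gaussianized data matrix.
#' @param drop_fracs fractions of rows to drop (default 0.05 to 0.75 in
#'   steps of 0.05, the probed grid of the CS convention).
#' @param B replicates per drop level.
#' @param seed integer seed.
#' @param gamma,nlambda,lambda_min_ratio selection settings.
#' @param method correlation flavour (`"spearman"` default).
#' @param cor_threshold,prob_threshold the 0.7 / 0.95 CS conventions.
#' @return list with `cs_coefficients` (named: strength, closeness,
#'   betweenness), and `detail`, the per-level proportion of replicates
#'   meeting the correlation threshold.
#' @export
case_drop_boot <- function(z, drop_fracs = seq(0.05, 0.75, by = 0.05),
                           B = 100, seed = NULL, gamma = 0.5,
                           nlambda = 100, lambda_min_ratio = 0.01,
                           method = "spearman", cor_threshold = 0.7,
                           prob_threshold = 0.95) {
  z <- as.matrix(z)
  n <- nrow(z)
  labels <- colnames(z) %||% paste0("x", seq_len(ncol(z)))
  colnames(z) <- labels
  if (any((1 - drop_fracs) * n < 50))
    stop("drop levels must leave at least 50 rows")
  full_net <- ggm_model_select(cor(z), n, gamma, nlambda, lambda_min_ratio,
                               labels)
  full_cent <- centrality(full_net)
  measures <- c("strength", "closeness", "betweenness")
  ok <- matrix(NA_real_, length(drop_fracs), length(measures),
               dimnames = list(paste0(drop_fracs), measures))
  with_seed(seed, {
    for (f in seq_along(drop_fracs)) {
      keep_n <- round((1 - drop_fracs[f]) * n)
      hits <- matrix(FALSE, B, length(measures))
      for (b in seq_len(B)) {
        rows <- sample.int(n, keep_n)
        cent <- tryCatch({
          net <- ggm_model_select(cor(z[rows, , drop = FALSE]), keep_n,
                                  gamma, nlambda, lambda_min_ratio, labels)
          centrality(net)
        }, error = function(e) NULL)
        if (is.null(cent)) next
        for (mi in seq_along(measures)) {
          r <- suppressWarnings(
            cor(full_cent[[measures[mi]]], cent[[measures[mi]]],
                method = method))
          hits[b, mi] <- is.finite(r) && r >= cor_threshold
        }
      }
      ok[f, ] <- colMeans(hits)
    }
  })
  cs <- vapply(measures, function(m) {
    qual <- ok[, m] >= prob_threshold
    run <- cumprod(qual) == 1  # all smaller fracs must qualify as well
    if (!any(run)) 0.0 else max(drop_fracs[run])
  }, numeric(1))
  list(cs_coefficients = cs, detail = ok, drop_fracs = drop_fracs)
}

#' Write bootstrap summaries as CSV
#'
#' @param result a `boot_result`.
#' @param dir output directory.
#' @param cs optional result of [case_drop_boot].
#' @return character vector of written paths.
#' @export
write_boot_summary <- function(result, dir, cs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- colnames(result$edge_draws)
  parts <- do.call(rbind, strsplit(nm, "--", fixed = TRUE))
  df <- data.frame(node1 = parts[, 1], node2 = parts[, 2],
                   estimate = unname(result$estimate),
                   ci_lo = result$ci[, "lo"], ci_hi = result$ci[, "hi"],
                   inclusion_freq = unname(result$inclusion_freq))
  paths <- file.path(dir, "boot_edges.csv")
  write.csv(df, paths, row.names = FALSE)
  dm <- edge_difference_matrix(result)
  p2 <- file.path(dir, "boot_edge_differences.csv")
  write.csv(data.frame(edge = rownames(dm), dm, check.names = FALSE),
            p2, row.names = FALSE)
  paths <- c(paths, p2)
  if (!is.null(cs)) {
    p3 <- file.path(dir, "boot_cs.csv")
    write.csv(data.frame(measure = names(cs$cs_coefficients),
                         cs = unname(cs$cs_coefficients)),
              p3, row.names = FALSE)
    paths <- c(paths, p3)
  }
  paths
}
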