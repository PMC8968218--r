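# Posterior model averaging of causal effects over a DAG sample.

# adjacency (parent x child) from one row of parent masks
masks_to_adjacency <- function(pm, p) {
  A <- matrix(FALSE, p, p)
  for (j in seq_len(p)) {
    i <- mask_nodes(pm[j], p)
    if (length(i)) A[i, j] <- TRUE
  }
  A
}

masks_acyclic <- function(pm, p) {
  !is.null(topological_order(masks_to_adjacency(pm, p)))
}

# boolean transitive closure: reach[i, j] = directed path i -> j
reachability <- function(A) {
  R <- A
  p <- nrow(A)
  for (k in seq_len(p))
    R <- R | (R %*% A > 0)
  R
}

#' Fit linear path coefficients of a DAG on standardized data
#'
#' For each node, the least-squares coefficients of its parents are
#' fitted on the gaussianized data (via the normal equations on the
#' cross-product matrix); nodes without parents get none.  Collinear
#' parents fall back to a minimum-norm solution with a warning.
#'
#' @param dag a [weighted_dag] (weights ignored), a logical adjacency
#'   matrix `[parent, child]`, or an integer parent-mask vector.
#' @param z gaussianized data matrix with columns matching the nodes.
#' @return a [weighted_dag] carrying the fitted coefficients.
#' @export
fit_path_coefficients <- function(dag, z) {
  z <- as.matrix(z)
  labels <- colnames(z) %||% paste0("x", seq_len(ncol(z)))
  A <- if (inherits(dag, "weighted_dag")) adjacency_matrix(dag)[labels, labels]
       else if (is.matrix(dag)) dag != 0
       else masks_to_adjacency(as.integer(dag), ncol(z))
  C <- crossprod(z)
  fit_paths_from_crossprod(A, C, labels)
}

fit_paths_from_crossprod <- function(A, C, labels) {
  p <- ncol(C)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (j in seq_len(p)) {
    pa <- which(A[, j])
    if (!length(pa)) next
    beta <- tryCatch(solve(C[pa, pa, drop = FALSE], C[pa, j]),
                     error = function(e) {
                       warning("collinear parents: minimum-norm solution used")
                       drop(MASS_ginv(C[pa, pa, drop = FALSE]) %*% C[pa, j])
                     })
    from <- c(from, pa); to <- c(to, rep(j, length(pa)))
    w <- c(w, as.numeric(beta))
  }
  weighted_dag(labels, cbind(labels[from], labels[to]), w)
}

# small pseudo-inverse (degenerate-parent fallback)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Total causal effect in a fitted DAG
#'
#' Sum over all directed paths from `source` to `target` of the products
#' of fitted coefficients: the `(source, target)` entry of
#' `(I - W)^-1 - I`.
#'
#' @param weighted a [weighted_dag] with fitted coefficients.
#' @param source,target node labels.
#' @return the total effect (0 when no path exists).
#' @export
total_effect <- function(weighted, source, target) {
  if (source == target) stop("source and target must differ")
  true_total_effect(weighted, source, target)
}

#' Posterior summary of the causal effect between two constructs
#'
#' For every sampled DAG the path coefficients are refitted, directed-
#' path existence is tested by graph reachability, and the total effect
#' is computed.  The summary follows the posterior-averaging convention
#' of the mixed-graph tables:
#' \itemize{
#'   \item `pathway_present_pct` — % of all sampled DAGs with a directed
#'     path `source -> target`;
#'   \item `causal_effect` and `ci90` — mean and equal-tailed 5th-95th
#'     percentile interval of the total effect over the path-present
#'     DAGs only;
#'   \item `direct_edge_pct` — % of the path-present DAGs containing the
#'     direct edge (a share of that subset, not of all DAGs);
#'   \item `direct_causal_effect` and `direct_ci90` — mean and interval
#'     of the direct edge's coefficient over the DAGs containing it.
#' }
#' When no sampled DAG links the pair, percentages are 0 and the effect
#' fields are `NA`.
#'
#' @param samples a `dag_sample_set`.
#' @param z gaussianized data matrix (columns matching the sample labels).
#' @param source,target construct labels.
#' @return a one-row data frame of class `effect_summary`.
#' @export
aggregate_effects <- function(samples, z, source, target) {
  stopifnot(inherits(samples, "dag_sample_set"))
  z <- as.matrix(z)
  per <- per_dag_effects(samples, z, source, target)
  total_n <- nrow(samples$parent_masks)
  present <- per$path_present
  n_present <- sum(per$count[present])
  out <- data.frame(source = source, target = target,
                    pathway_present_pct = 100 * n_present / total_n,
                    causal_effect = NA_real_, ci90_lo = NA_real_,
                    ci90_hi = NA_real_, direct_edge_pct = 0,
                    direct_causal_effect = NA_real_,
                    direct_ci90_lo = NA_real_, direct_ci90_hi = NA_real_)
  if (n_present > 0) {
    eff <- rep(per$effect[present], per$count[present])
    out$causal_effect <- mean(eff)
    qi <- quantile(eff, c(0.05, 0.95), names = FALSE)
    out$ci90_lo <- qi[1]; out$ci90_hi <- qi[2]
    direct <- present & per$direct
    n_direct <- sum(per$count[direct])
    out$direct_edge_pct <- 100 * n_direct / n_present
    if (n_direct > 0) {
      dco <- rep(per$direct_coef[direct], per$count[direct])
      out$direct_causal_effect <- mean(dco)
      qd <- quantile(dco, c(0.05, 0.95), names = FALSE)
      out$direct_ci90_lo <- qd[1]; out$direct_ci90_hi <- qd[2]
    }
  }
  class(out) <- c("effect_summary", "data.frame")
  out
}

# deduplicate the sampled structures and compute per-unique-DAG
# reachability, total effect and direct coefficient
per_dag_effects <- function(samples, z, source, target) {
  labels <- samples$labels
  si <- match(source, labels); ti <- match(target, labels)
  if (anyNA(c(si, ti))) stop("unknown construct label")
  if (source == target) stop("source and target must differ")
  pm <- samples$parent_masks
  key <- apply(pm, 1, paste, collapse = ".")
  tab <- table(key)
  ukeys <- names(tab)
  first <- match(ukeys, key)
  p <- samples$p
  C <- crossprod(z[, labels, drop = FALSE])
  effect <- numeric(length(ukeys))
  path_present <- logical(length(ukeys))
  direct <- logical(length(ukeys))
  direct_coef <- numeric(length(ukeys))
  for (u in seq_along(ukeys)) {
    A <- masks_to_adjacency(pm[first[u], ], p)
    R <- reachability(A)
    path_present[u] <- R[si, ti]
    direct[u] <- A[si, ti]
    if (path_present[u]) {
      wd <- fit_paths_from_crossprod(A, C, labels)
      W <- coef_matrix(wd)
      Tm <- solve(diag(p) - W) - diag(p)
      effect[u] <- Tm[si, ti]
      direct_coef[u] <- W[si, ti]
    }
  }
  list(count = as.integer(tab), effect = effect,
       path_present = path_present, direct = direct,
       direct_coef = direct_coef)
}

#' Share of mediated pathways through a given construct
#'
#' Among the sampled DAGs with a directed path `source -> target`, the
#' percentage in which at least one directed path passes through `via`
#' (equivalently: both legs `source -> via` and `via -> target` exist).
#'
#' @param samples a `dag_sample_set`.
#' @param z gaussianized data matrix.
#' @param source,target,via construct labels (`via` distinct from both).
#' @return the mediator share as a percentage (NA when no pathway at
#'   all is present).
#' @export
mediator_share <- function(samples, z, source, target, via) {
  if (via %in% c(source, target)) stop("via must differ from source and target")
  labels <- samples$labels
  vi <- match(via, labels)
  if (is.na(vi)) stop("unknown construct label")
  si <- match(source, labels); ti <- match(target, labels)
  pm <- samples$parent_masks
  key <- apply(pm, 1, paste, collapse = ".")
  tab <- table(key)
  first <- match(names(tab), key)
  n_present <- 0L; n_via <- 0L
  for (u in seq_along(first)) {
    A <- masks_to_adjacency(pm[first[u], ], samples$p)
    R <- reachability(A)
    if (R[si, ti]) {
      n_present <- n_present + tab[[u]]
      if (R[si, vi] && R[vi, ti]) n_via <- n_via + tab[[u]]
    }
  }
  if (n_present == 0L) return(NA_real_)
  100 * n_via / n_present
}

#' Table of posterior causal-effect summaries for one focal construct
#'
#' Applies [aggregate_effects] in both directions between `focal` and
#' every other construct, producing the two-block table shape used to
#' report posterior causal effects (each variable to the focal
#' construct, then the focal construct to each variable).
#'
#' @param samples a `dag_sample_set`.
#' @param z gaussianized data matrix.
#' @param focal the focal construct label.
#' @return data frame of stacked `effect_summary` rows with a
#'   `direction` column.
#' @export
effects_table <- function(samples, z, focal) {
  others <- setdiff(samples$labels, focal)
  to <- do.call(rbind, lapply(others, function(v)
    aggregate_effects(samples, z, v, focal)))
  from <- do.call(rbind, lapply(others, function(v)
    aggregate_effects(samples, z, focal, v)))
  to$direction <- "to_focal"
  from$direction <- "from_focal"
  out <- rbind(to, from)
  class(out) <- "data.frame"
  out
}

#' Threshold a DAG sample into a mixed graph
#'
#' For each unordered pair, the inclusion frequency is the share of all
#' sampled DAGs containing the edge in either orientation; pairs
#' strictly above `edge_threshold` are retained.  Among the retaining
#' DAGs, an arrowhead is drawn only when one orientation's share is
#' strictly above `direction_threshold`; otherwise the edge is emitted
#' undirected.  Both thresholds are strict (`"over"`).
#'
#' @param samples a `dag_sample_set`.
#' @param edge_threshold inclusion threshold (default 0.50).
#' @param direction_threshold orientation threshold (default 0.90).
#' @return an object of class `mixed_graph` with `nodes`,
#'   `directed_edges` (`from,to,inclusion_freq,direction_freq`) and
#'   `undirected_edges` (`node1,node2,inclusion_freq,direction_freq`).
#' @export
mixed_graph <- function(samples, edge_threshold = 0.50,
                        direction_threshold = 0.90) {
  stopifnot(inherits(samples, "dag_sample_set"),
            edge_threshold > 0, edge_threshold <= 1,
            direction_threshold > 0, direction_threshold <= 1)
  freq <- edge_inclusion_matrix(samples)
  labels <- samples$labels
  p <- samples$p
  dir_e <- data.frame(from = character(0), to = character(0),
                      inclusion_freq = numeric(0), direction_freq = numeric(0))
  und_e <- data.frame(node1 = character(0), node2 = character(0),
                      inclusion_freq = numeric(0), direction_freq = numeric(0))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    inc <- freq[i, j] + freq[j, i]   # orientations are mutually exclusive
    if (inc <= edge_threshold) next
    fij <- freq[i, j] / inc
    if (fij > direction_threshold) {
      dir_e[nrow(dir_e) + 1, ] <- list(labels[i], labels[j], inc, fij)
    } else if (1 - fij > direction_threshold) {
      dir_e[nrow(dir_e) + 1, ] <- list(labels[j], labels[i], inc, 1 - fij)
    } else {
      und_e[nrow(und_e) + 1, ] <- list(labels[i], labels[j], inc,
                                       max(fij, 1 - fij))
    }
  }
  structure(list(nodes = labels, directed_edges = dir_e,
                 undirected_edges = und_e,
                 edge_threshold = edge_threshold,
                 direction_threshold = direction_threshold),
            class = "mixed_graph")
}

#' @export
print.mixed_graph <- function(x, ...) {
  cat(sprintf("<mixed_graph> %d nodes, %d directed + %d undirected edges (> %.0f%% inclusion, > %.0f%% direction)\n",
              length(x$nodes), nrow(x$directed_edges),
              nrow(x$undirected_edges), 100 * x$edge_threshold,
              100 * x$direction_threshold))
  invisible(x)
}

#' Write the effects table and mixed graph
#'
#' @param effects data frame from [effects_table].
#' @param graph a `mixed_graph`.
#' @param dir output directory.
#' @return character vector of written paths.
#' @export
write_effects <- function(effects, graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "effects.csv")
  write.csv(effects, p1, row.names = FALSE)
  ig_edges <- rbind(
    if (nrow(graph$directed_edges))
      data.frame(from = graph$directed_edges$from,
                 to = graph$directed_edges$to,
                 inclusion_freq = graph$directed_edges$inclusion_freq,
                 direction_freq = graph$directed_edges$direction_freq,
                 directed = 1L),
    if (nrow(graph$undirected_edges))
      data.frame(from = graph$undirected_edges$node1,
                 to = graph$undirected_edges$node2,
                 inclusion_freq = graph$undirected_edges$inclusion_freq,
                 direction_freq = graph$undirected_edges$direction_freq,
                 directed = 0L))
  g <- igraph::graph_from_data_frame(
    ig_edges %||% data.frame(from = character(0), to = character(0)),
    directed = TRUE,
    vertices = data.frame(name = graph$nodes))
  p2 <- file.path(dir, "mixed_graph.graphml")
  p3 <- file.path(dir, "mixed_graph.dot")
  igraph::write_graph(g, p2, format = "graphml")
  igraph::write_graph(g, p3, format = "dot")
  c(p1, p2, p3)
}
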