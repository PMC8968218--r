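#' Sample a random weighted DAG
#'
#' Draws a uniformly random topological order, includes each forward pair
#' as an edge independently with probability `edge_prob`, and draws path
#' coefficients uniformly from `[-hi, -lo] U [lo, hi]`.  The lower bound
#' of the weight band must keep coefficients away from zero
#' (`lo >= 0.1`) so that true edges remain detectable in simulation.
#'
#' @param p number of nodes.
#' @param edge_prob edge inclusion probability in `[0, 1]`.
#' @param weight_range numeric `c(lo, hi)` band of absolute coefficients.
#' @param seed integer seed; the call is bit-reproducible given the seed.
#' @param labels optional node labels (default `x1..xp`).
#' @param noise_sd residual standard deviation used for every node.
#' @return a [weighted_dag].
#' @export
sample_random_dag <- function(p, edge_prob, weight_range = c(0.1, 0.9),
                              seed = NULL, labels = NULL, noise_sd = 1) {
  stopifnot(p >= 1)
  if (!is.numeric(edge_prob) || edge_prob < 0 || edge_prob > 1)
    stop("edge_prob must lie in [0, 1]")
  if (length(weight_range) != 2 || weight_range[1] > weight_range[2] ||
      weight_range[1] < 0.1)
    stop("weight_range must be an interval [lo, hi] with lo >= 0.1")
  if (is.null(labels)) labels <- paste0("x", seq_len(p))
  stopifnot(length(labels) == p)
  with_seed(seed, {
    ord <- sample.int(p)
    from <- integer(0); to <- integer(0)
    if (p >= 2) {
      for (a in 1:(p - 1)) for (b in (a + 1):p) {
        if (runif(1) < edge_prob) {
          from <- c(from, ord[a]); to <- c(to, ord[b])
        }
      }
    }
    w <- if (length(from)) {
      sample(c(-1, 1), length(from), replace = TRUE) *
        runif(length(from), weight_range[1], weight_range[2])
    } else numeric(0)
    edges <- cbind(labels[from], labels[to])
    weighted_dag(labels, edges, w,
                 stats::setNames(rep(noise_sd, p), labels))
  })
}

#' Simulate construct scores from a linear-Gaussian DAG
#'
#' Generates `n` rows of the structural model
#' `X_j = sum_{k in pa(j)} w_kj X_k + eps_j`, with independent Gaussian
#' residuals, visiting nodes in topological order.  The population
#' covariance is `(I - W)^-T D (I - W)^-1` with `D` the diagonal of
#' residual variances.
#'
#' @param dag a [weighted_dag].
#' @param n sample size.
#' @param seed integer seed.
#' @return numeric `n x p` matrix with node labels as column names.
#' @export
simulate_construct_scores <- function(dag, n, seed = NULL) {
  stopifnot(inherits(dag, "weighted_dag"), n >= 1)
  ord <- topological_order(dag)
  if (is.null(ord)) stop("dag is cyclic")
  W <- coef_matrix(dag)
  p <- length(dag$nodes)
  with_seed(seed, {
    X <- matrix(0, n, p, dimnames = list(NULL, dag$nodes))
    for (j in ord) {
      pa <- which(W[, j] != 0)
      mu <- if (length(pa)) X[, pa, drop = FALSE] %*% W[pa, j] else 0
      X[, j] <- mu + rnorm(n, sd = dag$noise_sd[j])
    }
    X
  })
}

#' Rescale residual SDs so every construct has unit marginal variance
#'
#' Path coefficients in this package are interpreted on the standardized
#' scale.  This helper chooses, in topological order, the residual
#' standard deviation `sqrt(1 - var(parent contribution))` for each
#' node, so that the implied marginal variances are exactly 1 and the
#' weights coincide with standardized total-effect components.  Errors
#' when a node's parents already contribute variance >= 1.
#'
#' @param dag a [weighted_dag].
#' @return the same DAG with recomputed `noise_sd`.
#' @export
unit_variance_noise <- function(dag) {
  stopifnot(inherits(dag, "weighted_dag"))
  ord <- topological_order(dag)
  W <- coef_matrix(dag)
  p <- length(dag$nodes)
  Sigma <- matrix(0, p, p, dimnames = dimnames(W))
  noise <- dag$noise_sd
  for (j in ord) {
    pa <- which(W[, j] != 0)
    expl <- if (length(pa))
      drop(t(W[pa, j]) %*% Sigma[pa, pa, drop = FALSE] %*% W[pa, j]) else 0
    if (expl >= 1)
      stop(sprintf("node %s: parents explain variance %.3f >= 1; weights too large",
                   dag$nodes[j], expl))
    noise[j] <- sqrt(1 - expl)
    # covariance of j with already-generated nodes
    for (i in ord[seq_len(match(j, ord) - 1)])
      Sigma[i, j] <- Sigma[j, i] <-
        if (length(pa)) sum(W[pa, j] * Sigma[pa, i]) else 0
    Sigma[j, j] <- 1
  }
  dag$noise_sd <- noise
  dag
}

# population covariance implied by a weighted DAG
implied_covariance <- function(dag) {
  W <- coef_matrix(dag)
  p <- nrow(W)
  Dm <- diag(dag$noise_sd[colnames(W)]^2, p)
  Minv <- solve(diag(p) - W)
  S <- t(Minv) %*% Dm %*% Minv
  dimnames(S) <- dimnames(W)
  S
}

#' Discretize construct scores into Likert item responses
#'
#' Emulates a one-factor measurement model per construct: each of the
#' `n_items` items is a noisy indicator of the (standardized) construct
#' score, `item = lambda * z + sqrt(1 - lambda^2) * noise`, cut at
#' equiprobable standard-normal thresholds into the item's response
#' range.  Reverse-coded items are emitted flipped
#' (`item_min + item_max - v`), so that scoring must un-flip them.
#'
#' @param scores numeric matrix of construct scores, one column per spec.
#' @param specs list of [scale_spec], one per score column (in order).
#' @param reliability item loading `lambda` in the open unit interval;
#'   scalar or one value per scale.
#' @param seed integer seed.
#' @return a `likert_dataset`: a list with integer item matrix `items`
#'   (columns named `<scale>_<item>`), `participant_id`, `specs`, and the
#'   column-to-scale map `item_scale`.
#' @export
likertize <- function(scores, specs, reliability = 0.8, seed = NULL) {
  specs <- as_scale_spec_list(specs)
  scores <- as.matrix(scores)
  if (ncol(scores) != length(specs))
    stop("need exactly one scale_spec per score column")
  lambda <- rep_len(reliability, length(specs))
  if (any(lambda <= 0) || any(lambda >= 1))
    stop("reliability must lie in the open interval (0, 1)")
  n <- nrow(scores)
  with_seed(seed, {
    cols <- list(); colnm <- character(0); item_scale <- character(0)
    for (s in seq_along(specs)) {
      sp <- specs[[s]]
      z <- scores[, s]
      zsd <- sd(z)
      if (!is.finite(zsd) || zsd == 0) stop("constant score column cannot be discretized")
      z <- (z - mean(z)) / zsd
      ncat <- sp$item_max - sp$item_min + 1L
      cuts <- qnorm(seq_len(ncat - 1) / ncat)
      for (it in seq_len(sp$n_items)) {
        latent <- lambda[s] * z + sqrt(1 - lambda[s]^2) * rnorm(n)
        v <- sp$item_min + findInterval(latent, cuts)
        if (it %in% sp$reverse_items) v <- sp$item_min + sp$item_max - v
        cols[[length(cols) + 1L]] <- as.integer(v)
        colnm <- c(colnm, paste0(sp$name, "_", it))
        item_scale <- c(item_scale, sp$name)
      }
    }
    items <- do.call(cbind, cols)
    colnames(items) <- colnm
    structure(list(items = items,
                   participant_id = seq_len(n),
                   specs = specs,
                   item_scale = item_scale),
              class = "likert_dataset")
  })
}

#' @export
print.likert_dataset <- function(x, ...) {
  cat(sprintf("<likert_dataset> %d participants x %d items (%d scales), %.1f%% missing\n",
              nrow(x$items), ncol(x$items), length(x$specs),
              100 * mean(is.na(x$items))))
  invisible(x)
}

#' Inject missing-completely-at-random cells
#'
#' Masks each item cell independently with probability `rate` (MCAR).
#' The missingness mask is recorded in the returned dataset.
#'
#' @param data a `likert_dataset`.
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @param scales optional character vector restricting masking to the
#'   named scales (used to exercise the per-scale exclusion filter).
#' @return the dataset with `NA` in masked cells and a logical `mask`.
#' @export
inject_missingness <- function(data, rate, seed = NULL, scales = NULL) {
  stopifnot(inherits(data, "likert_dataset"))
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("rate must lie in [0, 1)")
  items <- data$items
  with_seed(seed, {
    mask <- matrix(runif(length(items)) < rate, nrow(items), ncol(items))
    if (!is.null(scales)) mask[, !(data$item_scale %in% scales)] <- FALSE
    items[mask] <- NA_integer_
    out <- data
    out$items <- items
    out$mask <- mask | is.na(data$items)
    out
  })
}

#' Simulate a complete synthetic questionnaire study
#'
#' Bundles the generator stages: a random ground-truth DAG over the
#' scale battery (or a supplied one), linear-Gaussian construct scores,
#' Likert discretization, participant ages, and MCAR missingness.
#' Defaults mirror the emulated study's dimensions: 12 constructs,
#' n = 6161 respondents, ages drawn around mean 45.6 (SD 14.7).
#'
#' @param n number of respondents.
#' @param specs list of [scale_spec]; default [default_scale_specs()].
#' @param dag optional [weighted_dag] over the spec names; when `NULL` a
#'   random DAG with `edge_prob` and `weight_range` is drawn.
#' @param edge_prob,weight_range passed to [sample_random_dag].
#' @param reliability item loading per scale (scalar recycled).
#' @param missing_rate MCAR cell-missingness rate.
#' @param age_mean,age_sd normal age distribution parameters (years);
#'   ages are rounded and floored at 16 so that under-18 rows exercise
#'   the inclusion filter.
#' @param seed integer master seed for the whole simulation.
#' @return list with elements `data` (a `likert_dataset`), `ages`,
#'   `dag` (the ground truth), and `scores` (latent construct scores).
#' @export
simulate_study <- function(n = 6161, specs = default_scale_specs(),
                           dag = NULL, edge_prob = 0.25,
                           weight_range = c(0.15, 0.5), reliability = 0.8,
                           missing_rate = 0.02, age_mean = 45.6,
                           age_sd = 14.7, seed = 1) {
  specs <- as_scale_spec_list(specs)
  p <- length(specs)
  if (is.null(dag))
    dag <- sample_random_dag(p, edge_prob, weight_range,
                             seed = stage_seed(seed, "dag"),
                             labels = names(specs))
  stopifnot(identical(sort(dag$nodes), sort(names(specs))))
  scores <- simulate_construct_scores(dag, n, seed = stage_seed(seed, "scores"))
  scores <- scores[, names(specs), drop = FALSE]
  data <- likertize(scores, specs, reliability, seed = stage_seed(seed, "items"))
  if (missing_rate > 0)
    data <- inject_missingness(data, missing_rate,
                               seed = stage_seed(seed, "missing"))
  ages <- with_seed(stage_seed(seed, "ages"),
                    pmax(16L, as.integer(round(rnorm(n, age_mean, age_sd)))))
  list(data = data, ages = ages, dag = dag, scores = scores)
}

#' Write a Likert dataset as CSV plus a sidecar config
#'
#' The CSV has a header `participant_id[,age],<scale>_<item>...`; the
#' sidecar YAML records the scale specs and, when supplied, the true
#' generating DAG as a `parent,child,weight` edge list.
#'
#' @param data a `likert_dataset`.
#' @param csv_path,config_path output file paths.
#' @param ages optional age vector written as an `age` column.
#' @param dag optional [weighted_dag] stored in the sidecar.
#' @return invisibly, the two paths.
#' @export
write_likert_dataset <- function(data, csv_path, config_path = NULL,
                                 ages = NULL, dag = NULL) {
  stopifnot(inherits(data, "likert_dataset"))
  df <- data.frame(participant_id = data$participant_id)
  if (!is.null(ages)) df$age <- ages
  df <- cbind(df, as.data.frame(data$items))
  write.csv(df, csv_path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(config_path)) {
    cfg <- list(scales = lapply(unname(data$specs), function(sp)
      list(name = sp$name, n_items = sp$n_items, item_min = sp$item_min,
           item_max = sp$item_max,
           reverse_items = as.list(sp$reverse_items))))
    if (!is.null(dag)) {
      edge_lines <- if (nrow(dag$edges)) {
        paste(dag$edges[, 1], dag$edges[, 2],
              format(dag$weights, digits = 17, scientific = TRUE, trim = TRUE),
              sep = ",")
      } else character(0)
      cfg$true_dag <- list(nodes = as.list(dag$nodes),
                           edges = as.list(edge_lines))
    }
    yaml::write_yaml(cfg, config_path)
  }
  invisible(c(csv_path, config_path))
}

#' Read a Likert dataset written by [write_likert_dataset]
#'
#' @param csv_path,config_path the paths written by the writer.
#' @return list with `data` (a `likert_dataset`), `ages` (or `NULL`),
#'   and `dag` (the true [weighted_dag], or `NULL` when absent).
#' @export
read_likert_dataset <- function(csv_path, config_path) {
  cfg <- yaml::read_yaml(config_path)
  specs <- as_scale_spec_list(lapply(cfg$scales, function(s)
    scale_spec(s$name, s$n_items, s$item_min, s$item_max,
               unlist(s$reverse_items))))
  df <- read.csv(csv_path, check.names = FALSE)
  ages <- if ("age" %in% names(df)) df$age else NULL
  item_cols <- setdiff(names(df), c("participant_id", "age"))
  expected <- unlist(lapply(specs, function(sp) paste0(sp$name, "_", seq_len(sp$n_items))))
  if (!identical(sort(item_cols), sort(unname(expected))))
    stop("CSV item columns do not match the sidecar scale specs")
  items <- as.matrix(df[, unname(expected), drop = FALSE])
  storage.mode(items) <- "integer"
  data <- structure(list(items = items,
                         participant_id = df$participant_id,
                         specs = specs,
                         item_scale = rep(vapply(specs, `[[`, "", "name"),
                                          vapply(specs, `[[`, 0L, "n_items"))),
                    class = "likert_dataset")
  dag <- NULL
  if (!is.null(cfg$true_dag)) {
    lines <- unlist(cfg$true_dag$edges)
    if (length(lines)) {
      ed <- do.call(rbind, strsplit(lines, ","))
      dag <- weighted_dag(unlist(cfg$true_dag$nodes),
                          ed[, 1:2, drop = FALSE], as.numeric(ed[, 3]))
    } else {
      dag <- weighted_dag(unlist(cfg$true_dag$nodes))
    }
  }
  list(data = data, ages = ages, dag = dag)
}
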