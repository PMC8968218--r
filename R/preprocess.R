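#' Apply participant exclusion rules
#'
#' Implements the study's cohort filter in a fixed order, logging one
#' primary reason per removed row:
#' \enumerate{
#'   \item `age_ineligible` — age below `min_age` (inclusion criterion);
#'   \item `missingness` — missing fraction above `max_missing_frac` in
#'     ANY single scale;
#'   \item `age_outlier` — age strictly greater than
#'     `mean + age_sd_mult * SD`, with the mean and SD computed on the
#'     rows surviving the inclusion step.
#' }
#'
#' @param data a `likert_dataset`.
#' @param ages numeric vector aligned with the rows of `data`.
#' @param max_missing_frac per-scale missingness tolerance (default 0.20).
#' @param age_sd_mult multiplier of the age SD for the upper outlier rule.
#' @param min_age minimum eligible age (default 18).
#' @return list with `data` (the filtered dataset), `ages` (filtered),
#'   and `exclusions`, a data frame of `id, reason` for removed rows.
#' @export
filter_participants <- function(data, ages, max_missing_frac = 0.20,
                                age_sd_mult = 2.0, min_age = 18) {
  stopifnot(inherits(data, "likert_dataset"))
  n <- nrow(data$items)
  if (length(ages) != n) stop("ages must align with the dataset rows")
  reason <- rep(NA_character_, n)

  reason[!is.na(ages) & ages < min_age] <- "age_ineligible"

  eligible <- is.na(reason)
  for (sp in data$specs) {
    cols <- data$item_scale == sp$name
    frac <- rowMeans(is.na(data$items[, cols, drop = FALSE]))
    reason[eligible & frac > max_missing_frac] <- "missingness"
  }

  surv <- ages[is.na(reason) | reason == "missingness"]
  # mean/SD from the rows surviving the inclusion step
  cutoff <- mean(surv, na.rm = TRUE) + age_sd_mult * sd(surv, na.rm = TRUE)
  reason[is.na(reason) & !is.na(ages) & ages > cutoff] <- "age_outlier"

  keep <- is.na(reason)
  if (!any(keep)) stop("all participants excluded: empty cohort")
  out <- data
  out$items <- data$items[keep, , drop = FALSE]
  out$participant_id <- data$participant_id[keep]
  if (!is.null(data$mask)) out$mask <- data$mask[keep, , drop = FALSE]
  list(data = out, ages = ages[keep],
       exclusions = data.frame(id = data$participant_id[!keep],
                               reason = reason[!keep]),
       age_cutoff = cutoff)
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Cycles over item columns, regressing the observed values of each on
#' the current values of all other columns and filling its missing cells
#' by predictive mean matching (one of the `k` donors with closest
#' predicted value, drawn at random).  Observed cells are never altered;
#' imputed cells always lie in the item's observed support.  `m`
#' independent chains give `m` completed datasets.
#'
#' @param data a `likert_dataset` (missing cells as `NA`).
#' @param m number of completed datasets.
#' @param iterations chained-equation cycles per dataset.
#' @param seed integer seed; completions are bit-reproducible.
#' @param k number of predictive-mean-matching donors.
#' @return list of `m` completed `likert_dataset` objects.
#' @export
impute <- function(data, m = 5, iterations = 5, seed = NULL, k = 5) {
  stopifnot(inherits(data, "likert_dataset"), m >= 1, iterations >= 1)
  items <- data$items
  miss <- is.na(items)
  if (any(colSums(!miss) < 2))
    stop("every column needs at least 2 observed values")
  with_seed(seed, {
    lapply(seq_len(m), function(chain) {
      completed <- impute_one(items, miss, iterations, k)
      out <- data
      out$items <- completed
      out$mask <- miss
      out
    })
  })
}

impute_one <- function(items, miss, iterations, k) {
  p <- ncol(items)
  X <- items
  needs <- which(colSums(miss) > 0)
  # initialize by sampling observed values within each column
  for (j in needs) {
    obs <- items[!miss[, j], j]
    X[miss[, j], j] <- sample(obs, sum(miss[, j]), replace = TRUE)
  }
  if (!length(needs)) return(X)
  for (it in seq_len(iterations)) {
    for (j in needs) {
      yobs <- items[!miss[, j], j]
      if (length(unique(yobs)) == 1L) {
        warning(sprintf("column %s is constant among observed values; imputed by its mode",
                        colnames(items)[j]))
        X[miss[, j], j] <- yobs[1]
        next
      }
      Z <- cbind(1, X[, -j, drop = FALSE])
      storage.mode(Z) <- "double"
      fit <- stats::lm.fit(Z[!miss[, j], , drop = FALSE], as.numeric(yobs))
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred <- as.numeric(Z %*% beta)
      pobs <- pred[!miss[, j]]
      pmis <- pred[miss[, j]]
      filled <- vapply(pmis, function(pv) {
        donors <- order(abs(pobs - pv))[seq_len(min(k, length(pobs)))]
        yobs[donors[sample.int(length(donors), 1)]]
      }, numeric(1))
      X[miss[, j], j] <- filled
    }
  }
  storage.mode(X) <- "integer"
  X
}

#' Score scales with reverse coding
#'
#' Reverse-coded items are mapped `v -> item_min + item_max - v` before
#' summation; totals are integer valued and guaranteed to lie inside each
#' spec's score range.  A value outside an item's response range raises a
#' data-integrity error naming the row and column.
#'
#' @param data a fully observed `likert_dataset` (post-imputation), or an
#'   item matrix with columns named `<scale>_<item>` plus a `specs` list.
#' @param specs list of [scale_spec] (taken from the dataset if omitted).
#' @return integer matrix of scale totals, one column per scale.
#' @export
score_scales <- function(data, specs = NULL) {
  if (inherits(data, "likert_dataset")) {
    items <- data$items
    scale_of <- data$item_scale
    if (is.null(specs)) specs <- data$specs
  } else {
    items <- as.matrix(data)
    specs <- as_scale_spec_list(specs)
    scale_of <- sub("_[0-9]+$", "", colnames(items))
  }
  if (anyNA(items)) stop("score_scales requires complete data (impute first)")
  totals <- matrix(0L, nrow(items), length(specs),
                   dimnames = list(NULL, names(specs)))
  for (sp in specs) {
    cols <- which(scale_of == sp$name)
    if (length(cols) != sp$n_items)
      stop(sprintf("scale %s: expected %d items, found %d",
                   sp$name, sp$n_items, length(cols)))
    block <- items[, cols, drop = FALSE]
    bad <- which(block < sp$item_min | block > sp$item_max, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("value out of range for %s at row %d, column %s",
                   sp$name, bad[1, 1], colnames(block)[bad[1, 2]]))
    item_idx <- as.integer(sub("^.*_", "", colnames(block)))
    rev <- item_idx %in% sp$reverse_items
    if (any(rev))
      block[, rev] <- sp$item_min + sp$item_max - block[, rev, drop = FALSE]
    totals[, sp$name] <- as.integer(rowSums(block))
  }
  totals
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(var_i) / var_total)` with sample variances
#' (denominator `n - 1`).
#'
#' @param items numeric matrix of one scale's items (k >= 2 columns,
#'   n >= 3 rows).
#' @return the alpha coefficient.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items); n <- nrow(items)
  if (k < 2) stop("alpha needs at least 2 items")
  if (n < 3) stop("alpha needs at least 3 rows")
  vt <- var(rowSums(items))
  if (!is.finite(vt) || vt == 0) stop("zero total variance: alpha undefined")
  k / (k - 1) * (1 - sum(apply(items, 2, var)) / vt)
}

#' Rank-based inverse normal transformation
#'
#' Per column: ranks (ties averaged) are mapped through
#' `qnorm((rank - 0.5) / n)` and then centred and scaled to exact sample
#' mean 0 and SD 1.  The transform is strictly monotone in the input
#' (weakly under ties), so it is invariant to any strictly monotone
#' transformation of the raw column.
#'
#' @param totals numeric matrix (e.g. scale totals).
#' @return numeric matrix of gaussianized columns.
#' @export
gaussianize <- function(totals) {
  totals <- as.matrix(totals)
  n <- nrow(totals)
  out <- totals
  for (j in seq_len(ncol(totals))) {
    x <- totals[, j]
    if (length(unique(x)) < 2)
      stop(sprintf("column %s is constant: cannot gaussianize",
                   colnames(totals)[j] %||% j))
    z <- qnorm((rank(x, ties.method = "average") - 0.5) / n)
    out[, j] <- (z - mean(z)) / sd(z)
  }
  out
}

#' Run the full preprocessing stage
#'
#' Filter, impute (`m` chains), score, compute per-scale Cronbach's
#' alpha, and gaussianize.  Following the package's pooling convention,
#' the correlation matrix of the gaussianized totals is estimated in
#' each completed dataset and the `m` matrices are averaged; set `m = 1`
#' for a single stochastic imputation.
#'
#' @param data a `likert_dataset`.
#' @param ages ages aligned with the rows.
#' @param m number of imputations.
#' @param iterations chained-equation cycles.
#' @param seed integer seed.
#' @param max_missing_frac,age_sd_mult,min_age passed to
#'   [filter_participants].
#' @return an object of class `clean_dataset` with elements `totals`,
#'   `z` (first completed dataset), `S` (pooled correlation matrix),
#'   `kept_ids`, `exclusions`, `alphas`, `n`, and `m`.
#' @export
preprocess <- function(data, ages, m = 5, iterations = 5, seed = NULL,
                       max_missing_frac = 0.20, age_sd_mult = 2.0,
                       min_age = 18) {
  flt <- filter_participants(data, ages, max_missing_frac, age_sd_mult, min_age)
  completed <- impute(flt$data, m = m, iterations = iterations, seed = seed)
  per <- lapply(completed, function(d) {
    totals <- score_scales(d)
    z <- gaussianize(totals)
    list(totals = totals, z = z, S = cor(z))
  })
  S <- Reduce(`+`, lapply(per, `[[`, "S")) / length(per)
  alphas <- vapply(flt$data$specs, function(sp)
    cronbach_alpha(completed[[1]]$items[, flt$data$item_scale == sp$name,
                                        drop = FALSE]),
    numeric(1))
  structure(list(totals = per[[1]]$totals, z = per[[1]]$z, S = S,
                 kept_ids = flt$data$participant_id,
                 exclusions = flt$exclusions, alphas = alphas,
                 n = nrow(per[[1]]$z), m = m,
                 imputations = per),
            class = "clean_dataset")
}

#' @export
print.clean_dataset <- function(x, ...) {
  cat(sprintf("<clean_dataset> %d participants x %d scales (%d excluded, m = %d imputations)\n",
              x$n, ncol(x$totals), nrow(x$exclusions), x$m))
  invisible(x)
}
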