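# helper: a small complete dataset over the given specs
toy_dataset <- function(n, specs, seed = 1) {
  likertize(matrix(rnorm(n * length(specs)), n), specs, reliability = 0.8,
            seed = seed)
}

test_that("per-scale missingness rule removes rows above the 20% threshold", {
  specs <- list(scale_spec("cadlike", 13, 0, 4))
  ds <- toy_dataset(10, specs)
  ds$items[3, 1:3] <- NA  # 3 of 13 = 23% missing
  ds$items[5, 1:2] <- NA  # 15.4%: below threshold
  flt <- filter_participants(ds, ages = rep(30, 10))
  expect_equal(flt$exclusions$id, 3)
  expect_equal(flt$exclusions$reason, "missingness")
  expect_equal(nrow(flt$data$items), 9)
})

test_that("age outlier rule removes ages above mean + 2 SD of the eligible sample", {
  # construct ages with overall mean 45.6 and SD 14.7 that include a
  # 76-year-old: the cutoff lands at exactly 75.0
  n <- 25; mu <- 45.6; sdv <- 14.7
  u <- seq(-1, 1, length.out = n - 1)
  a <- (n * mu - 76) / (n - 1)
  bsq <- ((n - 1) * sdv^2 - (76 - mu)^2 - (n - 1) * (a - mu)^2) / sum(u^2)
  ages <- c(a + sqrt(bsq) * u, 76)
  expect_equal(mean(ages), mu)
  expect_equal(sd(ages), sdv)
  ds <- toy_dataset(n, list(scale_spec("s", 6, 0, 4)))
  flt <- filter_participants(ds, ages)
  expect_equal(flt$age_cutoff, mu + 2 * sdv)
  expect_equal(flt$exclusions$id, n)  # the 76-year-old, and only them
  expect_equal(flt$exclusions$reason, "age_outlier")
})

test_that("filter applies one primary reason in a fixed order and is idempotent on toys", {
  specs <- list(scale_spec("s", 5, 0, 4))
  ds <- toy_dataset(12, specs)
  ds$items[1, 1:2] <- NA           # 40% missing AND under-age: age wins
  ds$items[2, 1:2] <- NA           # 40% missing only
  ages <- rep(30, 12); ages[1] <- 16
  flt <- filter_participants(ds, ages)
  expect_equal(flt$exclusions$reason[flt$exclusions$id == 1], "age_ineligible")
  expect_equal(flt$exclusions$reason[flt$exclusions$id == 2], "missingness")

  # re-running on its own output removes nothing
  again <- filter_participants(flt$data, flt$ages)
  expect_equal(nrow(again$exclusions), 0)

  # clean table: nothing removed
  ok <- filter_participants(toy_dataset(8, specs), rep(30, 8))
  expect_equal(nrow(ok$exclusions), 0)

  expect_error(filter_participants(ds, rep(10, 12)), "empty cohort")
  expect_error(filter_participants(ds, rep(30, 5)), "align")
})

test_that("chained-equations imputation preserves observed cells and distributions", {
  specs <- list(scale_spec("a", 6, 0, 4), scale_spec("b", 4, 1, 5))
  ds <- toy_dataset(400, specs, seed = 2)
  complete <- ds$items
  dm <- inject_missingness(ds, 0.1, seed = 3)
  obs <- !is.na(dm$items)

  imps <- impute(dm, m = 3, iterations = 3, seed = 4)
  expect_length(imps, 3)
  for (im in imps) {
    expect_false(anyNA(im$items))
    expect_identical(im$items[obs], dm$items[obs])  # observed untouched
    # imputed values stay in the item's observed support
    for (j in seq_len(ncol(im$items)))
      expect_true(all(im$items[!obs[, j], j] %in% dm$items[obs[, j], j]))
  }
  # MCAR: imputed-value means track observed-value means
  for (j in seq_len(ncol(complete))) {
    if (all(obs[, j])) next
    se <- sd(dm$items[obs[, j], j]) / sqrt(sum(!obs[, j]))
    expect_lt(abs(mean(imps[[1]]$items[!obs[, j], j]) -
                    mean(dm$items[obs[, j], j])), 4 * se + 0.2)
  }
  # determinism and the no-missing identity
  expect_identical(impute(dm, m = 2, iterations = 2, seed = 9),
                   impute(dm, m = 2, iterations = 2, seed = 9))
  expect_identical(impute(ds, m = 2, iterations = 1, seed = 1)[[1]]$items,
                   ds$items)
})

test_that("constant observed column is imputed by its mode with a warning", {
  specs <- list(scale_spec("s", 3, 0, 4))
  ds <- toy_dataset(30, specs)
  ds$items[, 2] <- 2L
  ds$items[c(3, 7), 2] <- NA
  expect_warning(out <- impute(ds, m = 1, iterations = 1, seed = 1),
                 "constant")
  expect_true(all(out[[1]]$items[c(3, 7), 2] == 2L))
})

test_that("scale scoring reproduces published score ranges and reverse coding", {
  gse <- scale_spec("gse", 10, 1, 4)
  items <- matrix(4L, 3, 10,
                  dimnames = list(NULL, paste0("gse_", 1:10)))
  expect_true(all(score_scales(items, list(gse)) == 40L))

  ais <- scale_spec("ais", 30, 1, 6)
  items <- matrix(1L, 2, 30, dimnames = list(NULL, paste0("ais_", 1:30)))
  expect_true(all(score_scales(items, list(ais)) == 30L))

  # a reverse item answered at item_max contributes item_min
  rv <- scale_spec("rv", 2, 1, 5, reverse_items = 2L)
  items <- matrix(c(1L, 5L), 1, 2, dimnames = list(NULL, c("rv_1", "rv_2")))
  expect_equal(as.integer(score_scales(items, list(rv))), 1L + 1L)

  bad <- matrix(c(1L, 9L), 1, 2, dimnames = list(NULL, c("rv_1", "rv_2")))
  expect_error(score_scales(bad, list(rv)), "row 1, column rv_2")
})

test_that("Cronbach's alpha: exact cases, independence, and one-factor recovery", {
  x <- rnorm(50)
  expect_equal(cronbach_alpha(cbind(x, x)), 1)
  set.seed(5)
  expect_lt(abs(cronbach_alpha(matrix(rnorm(10000 * 8), 10000))), 0.05)
  expect_error(cronbach_alpha(cbind(rnorm(10))), "2 items")
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero total variance")

  # likertize alpha tracks a large-n oracle across loadings
  for (lam in c(0.4, 0.6, 0.8)) {
    sp <- list(scale_spec("s", 10, 0, 4))
    oracle <- cronbach_alpha(
      likertize(cbind(rnorm(100000)), sp, reliability = lam, seed = 20)$items)
    got <- cronbach_alpha(
      likertize(cbind(rnorm(5000)), sp, reliability = lam, seed = 21)$items)
    expect_lt(abs(got - oracle), 0.04)
  }
})

test_that("rank-based inverse normal transform is exact, monotone, and tie-consistent", {
  x <- c(1, 2, 2, 4)
  z <- gaussianize(cbind(x))
  expect_equal(z[2, 1], z[3, 1])               # ties share a z value
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-10)

  set.seed(6)
  y <- rnorm(500)
  zy <- gaussianize(cbind(y))[, 1]
  expect_equal(cor(y, zy, method = "spearman"), 1)
  # invariance to strictly monotone transforms of the input
  expect_equal(unname(gaussianize(cbind(exp(y)))),
               unname(gaussianize(cbind(y))))
  # distribution-free: output at least as normal as a normal input
  ks_in <- suppressWarnings(ks.test(y, "pnorm")$statistic)
  ks_out <- suppressWarnings(ks.test(zy, "pnorm")$statistic)
  expect_lte(ks_out, ks_in + 0.01)
  expect_error(gaussianize(cbind(rep(1, 10))), "constant")
})

test_that("preprocess assembles a coherent clean dataset", {
  study <- simulate_study(n = 300, seed = 30, missing_rate = 0.03)
  clean <- preprocess(study$data, study$ages, m = 2, iterations = 2, seed = 31)
  expect_s3_class(clean, "clean_dataset")
  expect_equal(nrow(clean$z), clean$n)
  expect_lt(max(abs(colMeans(clean$z))), 1e-8)
  expect_lt(max(abs(apply(clean$z, 2, sd) - 1)), 1e-6)
  expect_equal(length(clean$kept_ids), clean$n)
  expect_true(all(clean$exclusions$reason %in%
                    c("age_ineligible", "missingness", "age_outlier")))
  expect_true(isSymmetric(clean$S))
  for (sp in study$data$specs) {
    expect_true(all(clean$totals[, sp$name] >= sp$score_range[1] &
                      clean$totals[, sp$name] <= sp$score_range[2]))
  }
})
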