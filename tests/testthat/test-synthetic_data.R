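test_that("random DAG generator honours forced edge counts, bands, and seeds", {
  expect_equal(nrow(sample_random_dag(1, 0.7, seed = 1)$edges), 0L)
  expect_equal(nrow(sample_random_dag(12, 0, seed = 1)$edges), 0L)
  expect_equal(nrow(sample_random_dag(12, 1, seed = 1)$edges), 66L)
  d1 <- sample_random_dag(6, 0.4, c(0.2, 0.6), seed = 42)
  d2 <- sample_random_dag(6, 0.4, c(0.2, 0.6), seed = 42)
  expect_identical(d1, d2)
  expect_true(nrow(d1$edges) <= 15)
  expect_true(all(abs(d1$weights) >= 0.2 & abs(d1$weights) <= 0.6))
  expect_error(sample_random_dag(5, 1.5), "edge_prob")
  expect_error(sample_random_dag(5, 0.5, c(0.05, 0.5)), "weight_range")
  expect_error(sample_random_dag(5, 0.5, c(0.6, 0.2)), "weight_range")
})

test_that("weighted_dag validates structure", {
  expect_error(weighted_dag(c("a", "b"), rbind(c("a", "b"), c("b", "a")),
                            c(0.5, 0.5)), "cycle")
  expect_error(weighted_dag(c("a"), rbind(c("a", "a")), 0.5), "self-loops")
  expect_error(weighted_dag(c("a", "b"), rbind(c("a", "b")), numeric(0)),
               "one weight per edge")
  expect_error(weighted_dag(c("a", "b"), rbind(c("a", "b")), 0.5,
                            noise_sd = c(a = 1, b = 0)), "positive")
})

test_that("structural simulation matches its implied covariance", {
  # independence: empty DAG with unit noise
  d0 <- weighted_dag(letters[1:4])
  X <- simulate_construct_scores(d0, 10000, seed = 1)
  S <- crossprod(scale(X, scale = FALSE)) / 9999
  expect_lt(max(abs(S - diag(4))), 0.1)

  # chain with known marginal correlation
  dc <- weighted_dag(c("A", "B"), rbind(c("A", "B")), 0.8)
  Xc <- simulate_construct_scores(dc, 50000, seed = 2)
  expect_lt(abs(cor(Xc[, 1], Xc[, 2]) - 0.8 / sqrt(1.64)), 0.02)

  # determinism
  expect_identical(simulate_construct_scores(dc, 100, seed = 7),
                   simulate_construct_scores(dc, 100, seed = 7))
  expect_false(identical(simulate_construct_scores(dc, 100, seed = 7),
                         simulate_construct_scores(dc, 100, seed = 8)))
})

test_that("sample covariance converges to (I-W)^-T D (I-W)^-1", {
  for (s in 1:3) {
    d <- sample_random_dag(5, 0.5, c(0.2, 0.7), seed = s)
    Sig <- psynet:::implied_covariance(d)
    X <- simulate_construct_scores(d, 50000, seed = 100 + s)
    Shat <- crossprod(scale(X, scale = FALSE)) / (nrow(X) - 1)
    se <- sqrt((diag(Sig) %o% diag(Sig) + Sig^2) / nrow(X))
    expect_lt(max(abs(Shat - Sig) / se), 4)
  }
})

test_that("unit_variance_noise yields exactly unit marginal variances", {
  d <- unit_variance_noise(sample_random_dag(6, 0.4, c(0.2, 0.5), seed = 3))
  expect_equal(unname(diag(psynet:::implied_covariance(d))), rep(1, 6))
  toobig <- weighted_dag(c("a", "b", "c"),
                         rbind(c("a", "c"), c("b", "c")), c(0.9, 0.9))
  expect_error(unit_variance_noise(toobig), "too large")
})

test_that("likertize discretizes at stated ranges and near-unit loading collapses items", {
  sp <- scale_spec("bin", 5, 0, 1)
  z <- rnorm(2000)
  ds <- likertize(cbind(z), list(sp), reliability = 1 - 1e-9, seed = 4)
  agree <- mean(ds$items[, 1] == ds$items[, 2] & ds$items[, 2] == ds$items[, 3])
  expect_gt(agree, 0.999)

  # dissociation scale shape: 35 items scored 0-4 give totals in 0-140
  specs <- default_scale_specs()
  expect_equal(specs$cefsa$score_range, c(0L, 140L))
  sc <- matrix(rnorm(500 * 12), 500)
  ds12 <- likertize(sc, specs, reliability = 0.8, seed = 5)
  tot <- score_scales(ds12)
  for (sp in specs) {
    expect_true(all(tot[, sp$name] >= sp$score_range[1]))
    expect_true(all(tot[, sp$name] <= sp$score_range[2]))
  }
  expect_error(likertize(sc, specs, reliability = 1.2), "reliability")
})

test_that("emitted items reproduce the one-factor alpha of a large-sample oracle", {
  sp <- list(scale_spec("s", 20, 1, 4))
  oracle <- cronbach_alpha(
    likertize(cbind(rnorm(200000)), sp, reliability = 0.7, seed = 11)$items)
  got <- cronbach_alpha(
    likertize(cbind(rnorm(10000)), sp, reliability = 0.7, seed = 12)$items)
  expect_lt(abs(got - oracle), 0.03)
})

test_that("MCAR masking hits its target rate and is restorable by seed", {
  sp <- list(scale_spec("s", 50, 0, 4))
  ds <- likertize(cbind(rnorm(2000)), sp, seed = 6)
  expect_identical(inject_missingness(ds, 0, seed = 1)$items, ds$items)
  dm <- inject_missingness(ds, 0.1, seed = 2)
  expect_lt(abs(mean(is.na(dm$items)) - 0.1), 0.005)
  expect_identical(inject_missingness(ds, 0.1, seed = 2)$items, dm$items)
  expect_error(inject_missingness(ds, 1), "rate")

  # scale-restricted masking exercises the per-scale exclusion filter
  specs <- list(scale_spec("a", 10, 0, 4), scale_spec("bvs", 4, 0, 10))
  d2 <- likertize(matrix(rnorm(4000), 2000), specs, seed = 7)
  d2m <- inject_missingness(d2, 0.25, seed = 8, scales = "bvs")
  expect_true(all(!is.na(d2m$items[, d2m$item_scale == "a"])))
  frac <- rowMeans(is.na(d2m$items[, d2m$item_scale == "bvs"]))
  # P(at least one of 4 missing) = 1 - 0.75^4
  expect_lt(abs(mean(frac > 0.20) - (1 - 0.75^4)), 0.05)
})

test_that("true total effects: path products, absent paths, and the matrix identity", {
  chain <- weighted_dag(c("A", "B", "C"),
                        rbind(c("A", "B"), c("B", "C")), c(0.5, 0.5))
  expect_equal(true_total_effect(chain, "A", "C"), 0.25)
  expect_equal(true_total_effect(chain, "C", "A"), 0)
  expect_error(true_total_effect(chain, "A", "zzz"), "unknown")
  set.seed(9)
  for (r in 1:200) {
    p <- sample(2:8, 1)
    d <- sample_random_dag(p, 0.5, c(0.1, 0.9))
    nodes <- sample(d$nodes, 2)
    expect_equal(true_total_effect(d, nodes[1], nodes[2]),
                 psynet:::total_effect_by_paths(d, nodes[1], nodes[2]),
                 tolerance = 1e-10)
  }
})

test_that("datasets round-trip through CSV plus sidecar config", {
  study <- simulate_study(n = 60, seed = 13, missing_rate = 0.05)
  csv <- tempfile(fileext = ".csv"); ycf <- tempfile(fileext = ".yaml")
  write_likert_dataset(study$data, csv, ycf, ages = study$ages,
                       dag = study$dag)
  back <- read_likert_dataset(csv, ycf)
  expect_identical(back$data$items, study$data$items)
  expect_identical(back$ages, study$ages)
  expect_equal(back$dag$edges, study$dag$edges)
  expect_equal(back$dag$weights, study$dag$weights)
})
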