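test_that("local score: Occam behaviour, score equivalence, cache identity", {
  set.seed(41)
  z <- scale(matrix(rnorm(10000), 5000, 2))
  colnames(z) <- c("a", "b")
  # independent columns: the empty parent set wins
  expect_gt(local_score("a", character(0), z), local_score("a", "b", z))

  # bivariate score equivalence on dependent data
  zd <- cbind(a = rnorm(400))
  zd <- cbind(zd, b = 0.7 * zd[, 1] + rnorm(400))
  zd <- scale(zd)
  expect_equal(local_score("a", character(0), zd) + local_score("b", "a", zd),
               local_score("b", character(0), zd) + local_score("a", "b", zd),
               tolerance = 1e-10)

  # cached and uncached evaluation agree bit-exactly
  tb <- bge_score_tables(zd)
  expect_identical(local_score("b", "a", zd), local_score("b", "a", tb))
  expect_identical(local_score(1, 2, zd), local_score(1, 2, tb))
  expect_error(local_score("a", "a", zd), "exclude")
  expect_error(bge_score_tables(zd, score_config(aw = 2)), "aw")
})

test_that("Markov-equivalent DAGs score identically across covered-edge reversals", {
  set.seed(42)
  data_cache <- list()
  checked <- 0
  while (checked < 100) {
    p <- sample(3:8, 1)
    d <- sample_random_dag(p, 0.5, c(0.1, 0.8))
    A <- unname(adjacency_matrix(d))
    # find a covered edge: pa(child) = pa(parent) + parent
    cov_edge <- NULL
    for (e in seq_len(nrow(d$edges))) {
      i <- match(d$edges[e, 1], d$nodes); j <- match(d$edges[e, 2], d$nodes)
      if (setequal(which(A[, j]), c(which(A[, i]), i))) {
        cov_edge <- c(i, j); break
      }
    }
    if (is.null(cov_edge)) next
    key <- as.character(p)
    if (is.null(data_cache[[key]]))
      data_cache[[key]] <- bge_score_tables(
        scale(matrix(rnorm(60 * p), 60, p)))
    tb <- data_cache[[key]]
    A2 <- A
    A2[cov_edge[1], cov_edge[2]] <- FALSE
    A2[cov_edge[2], cov_edge[1]] <- TRUE
    expect_false(is.null(topological_order(A2)))  # reversal stays acyclic
    expect_equal(score_dag_total(tb, A), score_dag_total(tb, A2),
                 tolerance = 1e-8)
    checked <- checked + 1
  }
  expect_equal(checked, 100)
})

test_that("exact posterior: enumeration check, independence, orientation bound", {
  # p = 2 equals direct enumeration over the 3 DAGs
  set.seed(43)
  z <- cbind(a = rnorm(300))
  z <- scale(cbind(z, b = 0.5 * z[, 1] + rnorm(300)))
  colnames(z) <- c("a", "b")
  s0a <- local_score("a", character(0), z)
  s0b <- local_score("b", character(0), z)
  sab <- local_score("b", "a", z)
  sba <- local_score("a", "b", z)
  logw <- c(s0a + s0b, s0a + sab, s0b + sba)
  w <- exp(logw - max(logw))
  ep <- exact_edge_posterior(z)
  expect_equal(ep$edge_prob["a", "b"], w[2] / sum(w), tolerance = 1e-12)
  expect_equal(ep$edge_prob["b", "a"], w[3] / sum(w), tolerance = 1e-12)
  expect_equal(ep$log_evidence, max(logw) + log(sum(w)), tolerance = 1e-10)

  # independent columns: edges improbable (sampling noise occasionally
  # lifts one pair, so the check is the median over replicate datasets
  # of the worst edge)
  worst <- vapply(1:5, function(s) {
    set.seed(s * 11)
    max(exact_edge_posterior(scale(matrix(rnorm(2000 * 4), 2000, 4)))$edge_prob)
  }, numeric(1))
  expect_lt(median(worst), 0.05)

  # orientations are mutually exclusive events
  zd <- scale(simulate_construct_scores(
    sample_random_dag(5, 0.5, c(0.2, 0.6), seed = 44), 200, seed = 45))
  epd <- exact_edge_posterior(zd)$edge_prob
  expect_true(all(epd + t(epd) <= 1 + 1e-12))
  expect_true(all(diag(epd) == 0))
  expect_error(exact_edge_posterior(scale(matrix(rnorm(30 * 15), 30, 15))),
               "refusing")
})

test_that("both samplers recover the exact posterior and degenerate cases", {
  # p = 1: a single empty DAG
  z1 <- cbind(a = rnorm(50))
  for (smp in c("edge_mh", "partition")) {
    s1 <- sample_dags(scale(z1), iterations = 2000, seed = 1, sampler = smp)
    expect_true(all(s1$parent_masks == 0L))
  }

  # strong bivariate dependence: an edge in nearly every DAG
  set.seed(46)
  zb <- cbind(a = rnorm(2000))
  zb <- scale(cbind(zb, b = 3 * zb[, 1] + rnorm(2000) * sqrt(1 - 0.81)))
  sb <- sample_dags(zb, iterations = 5e4, seed = 2, sampler = "edge_mh")
  fr <- edge_inclusion_matrix(sb)
  expect_gt(fr[1, 2] + fr[2, 1], 0.99)

  # p = 5 fixture: MCMC inclusion frequencies track the exact oracle
  d <- sample_random_dag(5, 0.5, c(0.3, 0.6), seed = 5)
  z <- scale(simulate_construct_scores(d, 300, seed = 55))
  ep <- exact_edge_posterior(z)$edge_prob
  mh <- sample_dags(z, iterations = 2e5, seed = 6, sampler = "edge_mh")
  expect_lt(max(abs(edge_inclusion_matrix(mh) - ep)), 0.05)

  # retained-count contract and acyclicity of every stored structure
  pt <- sample_dags(z, iterations = 2e4, burn_in = 4e3, thinning = 8,
                    seed = 7, sampler = "partition")
  expect_equal(nrow(pt$parent_masks), floor((2e4 - 4e3) / 8))
  expect_true(all(apply(pt$parent_masks, 1, psynet:::masks_acyclic, p = 5)))
  expect_true(all(apply(mh$parent_masks, 1, psynet:::masks_acyclic, p = 5)))
  expect_true(all(is.finite(pt$score_trace)))

  # determinism under a fixed seed
  pt2 <- sample_dags(z, iterations = 2e4, burn_in = 4e3, thinning = 8,
                     seed = 7, sampler = "partition")
  expect_identical(pt$parent_masks, pt2$parent_masks)
})

test_that("an overwhelming edge penalty drives the posterior to the empty DAG", {
  d <- sample_random_dag(4, 0.6, c(0.3, 0.6), seed = 8)
  z <- scale(simulate_construct_scores(d, 500, seed = 9))
  tb <- bge_score_tables(z, score_config(edge_logprior = -1e4))
  s <- sample_dags(tb, iterations = 2e4, seed = 10, sampler = "edge_mh")
  expect_true(all(s$parent_masks == 0L))
})

test_that("convergence diagnostics compare chains and flag under-sampling", {
  d <- sample_random_dag(6, 0.4, c(0.3, 0.6), seed = 11)
  z <- scale(simulate_construct_scores(d, 300, seed = 12))
  c1 <- sample_dags(z, iterations = 1e5, seed = 13, sampler = "edge_mh")
  c1b <- sample_dags(z, iterations = 1e5, seed = 13, sampler = "edge_mh")
  c2 <- sample_dags(z, iterations = 1e5, seed = 14, sampler = "edge_mh")
  expect_equal(convergence_diagnostics(c1, c1b)$max_edge_discrepancy, 0)
  dd <- convergence_diagnostics(c1, c2)
  expect_lt(dd$max_edge_discrepancy, 0.05)
  expect_false(dd$flagged)

  # deliberately under-sampled chains on 12 constructs get flagged
  study <- simulate_study(n = 500, seed = 3, missing_rate = 0)
  zz <- gaussianize(score_scales(study$data))
  u1 <- sample_dags(zz, iterations = 3000, burn_in = 500, thinning = 1,
                    seed = 1, sampler = "edge_mh")
  u2 <- sample_dags(zz, iterations = 3000, burn_in = 500, thinning = 1,
                    seed = 2, sampler = "edge_mh")
  expect_true(convergence_diagnostics(u1, u2)$flagged)

  short <- sample_dags(z, iterations = 5e4, seed = 15, sampler = "edge_mh")
  expect_error(convergence_diagnostics(c1, short), "different settings")
})

test_that("DAG sample sets round-trip through the text format bit-exactly", {
  d <- sample_random_dag(5, 0.5, c(0.2, 0.6), seed = 16)
  z <- scale(simulate_construct_scores(d, 200, seed = 17))
  colnames(z) <- c("alpha", "beta", "gamma", "delta", "eps")
  s <- sample_dags(z, iterations = 1e4, seed = 18, sampler = "edge_mh")
  path <- tempfile(fileext = ".txt")
  write_dag_samples(s, path)
  back <- read_dag_samples(path)
  expect_identical(back$parent_masks, s$parent_masks)
  expect_identical(back$score_trace, s$score_trace)
  expect_identical(back$labels, s$labels)
  expect_equal(back$iterations, s$iterations)
  expect_equal(back$thinning, s$thinning)
})
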