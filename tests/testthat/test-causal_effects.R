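test_that("path coefficients are least squares on the standardized data", {
  # single edge: OLS consistency
  d <- weighted_dag(c("A", "B"), rbind(c("A", "B")), 0.5)
  d <- unit_variance_noise(d)
  z <- scale(simulate_construct_scores(d, 20000, seed = 51))
  colnames(z) <- d$nodes
  fit <- fit_path_coefficients(d, z)
  expect_equal(fit$weights, 0.5, tolerance = 0.05)
  expect_lt(abs(fit$weights - 0.5), 0.02)

  # empty DAG: no coefficients
  fit0 <- fit_path_coefficients(weighted_dag(c("A", "B")), z)
  expect_equal(nrow(fit0$edges), 0)

  # agreement with lm() as the independent solver
  d3 <- sample_random_dag(4, 0.6, c(0.2, 0.6), seed = 52)
  z3 <- scale(simulate_construct_scores(d3, 500, seed = 53))
  colnames(z3) <- d3$nodes
  fit3 <- fit_path_coefficients(d3, z3)
  W <- coef_matrix(fit3)
  A <- adjacency_matrix(d3)
  for (j in seq_len(4)) {
    pa <- which(A[, j])
    if (!length(pa)) next
    ref <- coef(lm(z3[, j] ~ z3[, pa, drop = FALSE] - 1))
    expect_equal(unname(W[pa, j]), unname(ref), tolerance = 1e-8)
  }
})

test_that("total effect equals the path-product sum and the matrix identity", {
  chain <- weighted_dag(c("a", "b", "c"),
                        rbind(c("a", "b"), c("b", "c")), c(0.5, 0.5))
  expect_equal(total_effect(chain, "a", "c"), 0.25)
  expect_equal(total_effect(chain, "c", "a"), 0)
  expect_error(total_effect(chain, "a", "a"), "differ")
  set.seed(54)
  for (r in 1:100) {
    d <- sample_random_dag(sample(3:10, 1), 0.4, c(0.1, 0.9))
    ends <- sample(d$nodes, 2)
    expect_equal(total_effect(d, ends[1], ends[2]),
                 psynet:::total_effect_by_paths(d, ends[1], ends[2]),
                 tolerance = 1e-10)
  }
})

test_that("aggregate_effects reproduces a hand-computed 4-DAG fixture", {
  set.seed(55)
  z <- scale(matrix(rnorm(200 * 3), 200, 3))
  colnames(z) <- c("A", "B", "C")
  fix <- make_sample_set(list(
    rbind(c("A", "B")),                                # direct only
    rbind(c("A", "B"), c("C", "B")),                   # direct, adjusted
    rbind(c("A", "B"), c("A", "C"), c("C", "B")),      # direct + indirect
    rbind(c("C", "A"), c("C", "B"))                    # no A->B path
  ), c("A", "B", "C"))

  # hand computation with lm()
  b1 <- unname(coef(lm(z[, "B"] ~ z[, "A"] - 1)))
  b2 <- unname(coef(lm(z[, "B"] ~ z[, c("A", "C")] - 1)))
  a3 <- unname(coef(lm(z[, "C"] ~ z[, "A"] - 1)))
  tot <- c(b1, b2[1], b2[1] + a3 * b2[2])
  es <- aggregate_effects(fix, z, "A", "B")
  expect_equal(es$pathway_present_pct, 75)
  expect_equal(es$direct_edge_pct, 100)
  expect_equal(es$causal_effect, mean(tot))
  expect_equal(es$ci90_lo, unname(quantile(tot, 0.05)))
  expect_equal(es$ci90_hi, unname(quantile(tot, 0.95)))
  expect_equal(es$direct_causal_effect, mean(c(b1, b2[1], b2[1])))

  # no pathway at all
  none <- aggregate_effects(fix, z, "B", "A")
  expect_equal(none$pathway_present_pct, 0)
  expect_true(is.na(none$causal_effect))

  # acyclicity bookkeeping: no DAG carries paths in both directions
  fwd <- psynet:::per_dag_effects(fix, z, "A", "B")
  bwd <- psynet:::per_dag_effects(fix, z, "B", "A")
  expect_equal(sum(fwd$count[fwd$path_present & bwd$path_present]), 0)
})

test_that("direct_edge_pct is a share of the path-present subset", {
  # pathway in 2 of 4 DAGs; direct edge in 1 of those 2
  set.seed(56)
  z <- scale(matrix(rnorm(100 * 3), 100, 3))
  colnames(z) <- c("A", "B", "C")
  fix <- make_sample_set(list(
    rbind(c("A", "B")),                     # direct
    rbind(c("A", "C"), c("C", "B")),        # indirect only
    rbind(c("B", "A")),                     # reverse
    NULL                                    # empty
  ), c("A", "B", "C"))
  es <- aggregate_effects(fix, z, "A", "B")
  expect_equal(es$pathway_present_pct, 50)   # 2 of 4 sampled DAGs
  expect_equal(es$direct_edge_pct, 50)       # 1 of those 2
})

test_that("mediator share counts paths through the given construct", {
  set.seed(57)
  z <- scale(matrix(rnorm(100 * 3), 100, 3))
  colnames(z) <- c("A", "M", "B")
  chain_only <- make_sample_set(list(rbind(c("A", "M"), c("M", "B"))),
                                c("A", "M", "B"))
  expect_equal(mediator_share(chain_only, z, "A", "B", "M"), 100)
  direct_only <- make_sample_set(list(rbind(c("A", "B"))), c("A", "M", "B"))
  expect_equal(mediator_share(direct_only, z, "A", "B", "M"), 0)
  expect_error(mediator_share(chain_only, z, "A", "B", "A"), "differ")

  # mixed fixture of 10 enumerated DAGs: 6 path-present, 4 via M
  lists <- c(
    replicate(4, rbind(c("A", "M"), c("M", "B")), simplify = FALSE),
    replicate(2, rbind(c("A", "B")), simplify = FALSE),
    replicate(3, rbind(c("M", "A"), c("M", "B")), simplify = FALSE),
    list(NULL))
  mixed <- make_sample_set(lists, c("A", "M", "B"))
  expect_equal(mediator_share(mixed, z, "A", "B", "M"), 100 * 4 / 6)
})

test_that("mixed graph applies strict thresholds at the boundary", {
  labels <- c("a", "b", "c")
  rows <- vector("list", 16)
  for (r in 1:16) {
    e <- NULL
    if (r <= 8) e <- rbind(e, if (r <= 4) c("a", "b") else c("b", "a"))
    if (r <= 9) e <- rbind(e, c("a", "c")) else if (r == 10) e <- rbind(e, c("c", "a"))
    if (r <= 11) e <- rbind(e, c("b", "c")) else if (r == 12) e <- rbind(e, c("c", "b"))
    rows[r] <- list(e)
  }
  fix <- make_sample_set(rows, labels)
  mg <- mixed_graph(fix)
  # pair (a,b): inclusion exactly 8/16 = 0.50 -> excluded ("over" is strict)
  all_pairs <- rbind(mg$directed_edges[, 1:2],
                     setNames(mg$undirected_edges[, 1:2], c("from", "to")))
  expect_false(any(apply(all_pairs, 1, setequal, c("a", "b"))))
  # pair (a,c): 10/16 retained, orientation exactly 9/10 = 0.90 -> undirected
  expect_true(any(apply(mg$undirected_edges[, 1:2], 1, setequal, c("a", "c"))))
  # pair (b,c): 12/16 retained, orientation 11/12 > 0.90 -> arrow b -> c
  expect_true(any(mg$directed_edges$from == "b" & mg$directed_edges$to == "c"))

  # all DAGs identical: every edge retained and arrowed
  same <- make_sample_set(replicate(5, rbind(c("a", "b"), c("b", "c")),
                                    simplify = FALSE), labels)
  mgs <- mixed_graph(same)
  expect_equal(nrow(mgs$directed_edges), 2)
  expect_equal(nrow(mgs$undirected_edges), 0)

  # 60/40 split on orientation: retained but undirected
  split <- make_sample_set(c(replicate(3, rbind(c("a", "b")), simplify = FALSE),
                             replicate(3, rbind(c("b", "a")), simplify = FALSE)),
                           labels)
  mgu <- mixed_graph(split)
  expect_equal(nrow(mgu$directed_edges), 0)
  expect_equal(nrow(mgu$undirected_edges), 1)
})

test_that("effects table and mixed graph artifacts are written", {
  d <- identifiable_dag6()
  z <- scale(simulate_construct_scores(d, 500, seed = 58))
  colnames(z) <- d$nodes
  s <- sample_dags(z, iterations = 2e4, seed = 59, sampler = "edge_mh")
  eff <- effects_table(s, z, "x3")
  expect_equal(nrow(eff), 10)  # five constructs, both directions
  expect_true(all(eff$pathway_present_pct >= 0 & eff$pathway_present_pct <= 100))
  dir <- tempfile()
  paths <- write_effects(eff, mixed_graph(s), dir)
  expect_true(all(file.exists(paths)))
})
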