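test_that("simulators are reproducible under a fixed seed", {
  s <- scenario_spec(rho = 0.5, N = 5000, seed = 99)
  a <- run_collider_sim(s)
  b <- run_collider_sim(s)
  expect_identical(a$estimate, b$estimate)
  expect_identical(a$strata, b$strata)
  sel1 <- run_selection_sim(scenario_spec(N = 5000, seed = 100))
  sel2 <- run_selection_sim(scenario_spec(N = 5000, seed = 100))
  expect_identical(sel1$calibration, sel2$calibration)
  expect_identical(sel1$ks$statistic, sel2$ks$statistic)
})

test_that("collider regimes show the predicted conditional association signs", {
  N <- 5e4
  # prior-association path only: positive
  pos <- run_collider_sim(scenario_spec(rho = 0.5, r = 0, N = N, seed = 1))
  expect_gt(pos$estimate, 3 * pos$se)
  expect_gt(pos$partial_cor, 0)
  # residual (collider) path only: negative
  neg <- run_collider_sim(scenario_spec(rho = 0, r = 0.8, N = N, seed = 1))
  expect_lt(neg$estimate, -3 * neg$se)
  expect_lt(neg$partial_cor, 0)
  # both paths absent: null
  nil <- run_collider_sim(scenario_spec(rho = 0, r = 0, N = N, seed = 1))
  expect_lt(abs(nil$estimate), 3 * nil$se)
})

test_that("collider windowing errors when strata cannot be formed", {
  expect_error(run_collider_sim(scenario_spec(N = 20, seed = 3,
                                              window = 0.01)),
               "window")
  expect_error(run_collider_sim(scenario_spec(K = 3, N = 100, seed = 1)),
               "K = 2")
})

test_that("selection reporting leaves the posterior untouched and calibrated", {
  spec <- scenario_spec(pi = 0.5, rho = 0, mu = 2, N = 4e4, seed = 7)
  out <- run_selection_sim(spec)
  # structural invariance: the selected test's reported posterior is the
  # plain marginal posterior of that test, recomputed with no selection
  set.seed(spec$seed)
  theta <- bayesmt:::.simulate_truth(spec$prior, spec$N)
  X <- bayesmt:::.simulate_z(spec$model, theta)
  i <- 17L
  res <- joint_posterior(spec$prior, spec$model, evidence_vector(X[i, ], "z"))
  marg <- bayesmt:::.batch_marginals(spec$prior, spec$model, X)
  expect_equal(marg[i, ], res$marginal_alt, tolerance = 1e-10)
  # calibration: per-bin empirical frequency tracks the posterior
  cal <- out$calibration[out$calibration$n >= 200, ]
  expect_gt(nrow(cal), 3)
  expect_true(all(abs(cal$empirical_freq - cal$mean_posterior) <=
                    3 * cal$se + 1 / (2 * cal$n)))
  # selected null p-values are not uniform
  expect_gt(out$ks$statistic, out$ks$critical_0.01)
})

test_that("a single-replicate selection run degrades with a warning", {
  expect_warning(run_selection_sim(scenario_spec(N = 1, seed = 5)),
                 "degenerate")
})

test_that("operating characteristics recover closed-form error rates", {
  # all-null truth, independent tests: FWER of unadjusted testing is
  # 1 - 0.95^K; Bonferroni stays at or below alpha; K = 1 equals alpha
  oc8 <- run_operating_characteristics(
    scenario_spec(K = 8, pi = 0.5, N = 2e4, seed = 11), truth_pi = 0)
  un <- oc8[oc8$method == "unadjusted", ]
  expect_lt(abs(un$fwer - (1 - 0.95^8)), 3 * un$fwer_se)
  bf <- oc8[oc8$method == "bonferroni", ]
  expect_lt(bf$fwer, 0.05 + 3 * bf$fwer_se)
  oc1 <- run_operating_characteristics(
    scenario_spec(K = 1, pi = 0.5, N = 2e4, seed = 12), truth_pi = 0)
  un1 <- oc1[oc1$method == "unadjusted", ]
  expect_lt(abs(un1$fwer - 0.05), 3 * un1$fwer_se)
  # with signal present, every method has positive power and the
  # posterior rule reports all columns
  occ <- run_operating_characteristics(
    scenario_spec(K = 4, pi = 0.5, mu = 3, N = 5e3, seed = 13))
  expect_true(all(occ$power > 0.5))
  expect_true(all(occ$fdr >= 0 & occ$fdr <= 1))
})

test_that("generated datasets are deterministic and round-trip the readers", {
  dir1 <- tempfile(); dir2 <- tempfile()
  spec <- scenario_spec(K = 8, pi = 0.3, N = 1, seed = 21)
  f1 <- generate_dataset(spec, dir1)
  f2 <- generate_dataset(spec, dir2)
  expect_identical(readLines(f1$evidence), readLines(f2$evidence))
  expect_identical(readLines(f1$truth), readLines(f2$truth))
  back <- read_evidence(f1$evidence)
  expect_equal(back$schema, "z")
  expect_equal(back$evidence$K, 8L)
  # all-null generator writes an all-zero truth file
  f0 <- generate_dataset(scenario_spec(K = 8, pi = 0, N = 1, seed = 22),
                         tempfile())
  truth <- read.csv(f0$truth, comment.char = "#")
  expect_true(all(truth$theta == 0))
})

test_that("perfect prior association never generates discordant truths", {
  pr <- common_cause_prior(0.5, 1, 2)
  set.seed(23)
  theta <- bayesmt:::.simulate_truth(pr, 1e4)
  expect_equal(sum(theta[, 1] != theta[, 2]), 0L)
})
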