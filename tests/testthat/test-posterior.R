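test_that("frozen two-test posteriors match their closed forms", {
  m <- evidence_model(2, mu = 2)
  x <- evidence_vector(c(2, 2), "z")
  # independent prior: per-test phi(0) / (phi(2) + phi(0))
  res <- joint_posterior(independent_prior(c(0.5, 0.5)), m, x)
  expect_equal(res$marginal_alt, rep(dnorm(0) / (dnorm(2) + dnorm(0)), 2),
               tolerance = 1e-12)
  expect_equal(res$marginal_alt, c(0.8807971, 0.8807971), tolerance = 1e-6)
  # perfectly associated prior: pooled two-observation Bayes factor
  res1 <- joint_posterior(common_cause_prior(0.5, 1, 2), m, x)
  expect_equal(res1$marginal_alt,
               rep(dnorm(0)^2 / (dnorm(2)^2 + dnorm(0)^2), 2),
               tolerance = 1e-12)
  expect_equal(res1$marginal_alt, c(0.9820138, 0.9820138), tolerance = 1e-6)
})

test_that("a flat likelihood returns the prior untouched", {
  m0 <- evidence_model(2, mu = 0)
  pr <- common_cause_prior(0.3, 0.6, 2)
  res <- joint_posterior(pr, m0, evidence_vector(c(1.7, -0.4), "z"))
  expect_equal(res$joint, prior_table(pr)$prob, tolerance = 1e-12)
})

test_that("the engine agrees with a direct-sum enumeration oracle", {
  set.seed(13)
  for (rep in 1:15) {
    K <- sample(2:4, 1)
    pr <- common_cause_prior(runif(1, 0.1, 0.9), runif(1), K)
    use_R <- rep %% 2 == 0
    R <- if (use_R) equicorrelation(K, runif(1, 0.1, 0.7)) else NULL
    mu <- runif(K, 0.5, 3)
    m <- evidence_model(K, mu = mu, R = R)
    x <- rnorm(K, sd = 1.5)
    lik <- if (use_R) {
      function(x, cfg) oracle_dmvnorm(x, mu * cfg, R)
    } else {
      function(x, cfg) prod(dnorm(x, mu * cfg, 1))
    }
    tab <- prior_table(pr)
    want <- oracle_posterior(tab$configs, tab$prob, lik, x)
    got <- joint_posterior(pr, m, evidence_vector(x, "z"))
    expect_equal(got$joint, want$joint, tolerance = 1e-10)
    expect_equal(got$marginal_alt, want$marginal, tolerance = 1e-10)
  }
})

test_that("joint mass and marginals stay mutually consistent", {
  set.seed(17)
  for (rep in 1:10) {
    K <- sample(1:5, 1)
    pr <- if (rep %% 2) independent_prior(runif(K, 0.1, 0.9)) else
      common_cause_prior(runif(1, 0.1, 0.9), runif(1), K)
    m <- evidence_model(K, mu = runif(K, 0, 3))
    res <- joint_posterior(pr, m, evidence_vector(rnorm(K), "z"))
    expect_lt(abs(sum(res$joint) - 1), 1e-10)
    expect_equal(res$marginal_alt,
                 as.numeric(crossprod(res$configs, res$joint)),
                 tolerance = 1e-10)
  }
})

test_that("a priori association makes other tests' data informative", {
  m <- evidence_model(2, mu = 2)
  x <- evidence_vector(c(2.5, 2.5), "z")
  at_rho0 <- marginal_posterior(independent_prior(c(0.5, 0.5)), m, x, 1)
  at_rho9 <- marginal_posterior(common_cause_prior(0.5, 0.9, 2), m, x, 1)
  expect_gt(at_rho9, at_rho0)
  # and perturbing the OTHER test's data now moves this test's posterior
  x2 <- evidence_vector(c(2.5, -1), "z")
  expect_false(isTRUE(all.equal(
    marginal_posterior(common_cause_prior(0.5, 0.9, 2), m, x2, 1), at_rho9)))
})

test_that("exchangeable evidence at rho = 1 gives equal marginals", {
  K <- 4
  pr <- common_cause_prior(0.4, 1, K)
  m <- evidence_model(K, mu = 2)
  res <- joint_posterior(pr, m, evidence_vector(c(2.1, -0.3, 1.2, 0.4), "z"))
  expect_lt(diff(range(res$marginal_alt)), 1e-10)
})

test_that("single-test posterior handles edge priors and log-space extremes", {
  expect_equal(single_test_posterior(0.5, -1, -1), 0.5)
  expect_equal(single_test_posterior(0.5, dnorm(2, 0, 1, TRUE),
                                     dnorm(2, 2, 1, TRUE)),
               0.8807971, tolerance = 1e-6)
  expect_equal(single_test_posterior(0, -1e6, 0), 0)
  expect_equal(single_test_posterior(1, 0, -1e6), 1)
  # huge log-likelihood gaps neither overflow nor NaN
  expect_equal(single_test_posterior(0.5, -1e8, 0), 1)
  expect_equal(single_test_posterior(0.5, 0, -1e8), 0)
})

test_that("enumeration stays finite and normalized for larger K and extreme data", {
  K <- 15
  pr <- common_cause_prior(0.2, 0.5, K)
  m <- evidence_model(K, mu = 3)
  x <- evidence_vector(c(rep(8, 7), rep(-8, 8)), "z")
  res <- joint_posterior(pr, m, x)
  expect_true(all(is.finite(res$marginal_alt)))
  expect_true(all(res$marginal_alt >= 0 & res$marginal_alt <= 1))
  expect_lt(abs(sum(res$joint) - 1), 1e-10)
})

test_that("decisions use a strict threshold with boundary ties kept null", {
  res <- structure(list(marginal_alt = c(0.88, 0.12), K = 2,
                        configs = matrix(0, 1, 2), joint = 1,
                        log_normalizer = 0),
                   class = "posterior_result")
  expect_equal(decide(res, 0.5), c(TRUE, FALSE))
  res$marginal_alt <- 0.5
  expect_false(decide(res, 0.5))
  res$marginal_alt <- c(0.982, 0.982)
  expect_equal(decide(res, 0.9), c(TRUE, TRUE))
  expect_error(decide(res, 1), "tau")
})

test_that("index and dimension violations are explicit", {
  pr <- independent_prior(c(0.5, 0.5))
  m <- evidence_model(2)
  x <- evidence_vector(c(1, 1), "z")
  expect_error(marginal_posterior(pr, m, x, 3), "out of range")
  expect_error(marginal_posterior(pr, m, x, 0), "out of range")
  expect_error(joint_posterior(pr, evidence_model(3), x), "mismatch")
  expect_error(joint_posterior(pr, m, evidence_vector(c(1, 1, 1), "z")),
               "mismatch")
})

test_that("posteriors are calibrated over forward simulations", {
  # among replicates whose computed posterior is near q, the alternative
  # is true with frequency q
  set.seed(23)
  N <- 2e5
  pr <- common_cause_prior(0.5, 0.3, 2)
  m <- evidence_model(2, mu = 2)
  theta <- bayesmt:::.simulate_truth(pr, N)
  X <- bayesmt:::.simulate_z(m, theta)
  marg <- bayesmt:::.batch_marginals(pr, m, X)
  q1 <- marg[, 1]
  for (q in c(0.2, 0.5, 0.8)) {
    in_bin <- abs(q1 - q) <= 0.01
    n <- sum(in_bin)
    expect_gt(n, 200)
    emp <- mean(theta[in_bin, 1])
    target <- mean(q1[in_bin])
    se <- sqrt(target * (1 - target) / n)
    expect_lt(abs(emp - target), 3 * se + 1 / (2 * n))
  }
})
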