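# Seeded Monte-Carlo experiments around the exact posterior engine:
#   * collider reversal -- conditioning on one test's statistic opens a
#     path that can make the other test's statistic evidence AGAINST a
#     hypothesis it would naively support;
#   * selective reporting -- posteriors stay calibrated under a
#     report-the-larger-posterior selection rule, while the selected null
#     p-values stop being uniform;
#   * operating characteristics -- FWER / power / FDR of the posterior
#     threshold rule against Bonferroni, Holm and BH.
# The same machinery doubles as the synthetic-data generator for tests.

#' Scenario specification for the simulators
#'
#' Encodes the generative structure: K tests whose indicators come from a
#' common-cause exchangeable prior (shared probability \code{pi},
#' association \code{rho}) and whose z-statistics are N(mu * theta, 1) with
#' residual equicorrelation \code{r} given theta.
#'
#' @param K number of tests; default 2.
#' @param pi prior alternative probability; default 0.5.
#' @param rho prior association in [0,1]; default 0.
#' @param mu alternative mean shift on the z scale; default 2.
#' @param r residual correlation between statistics given theta; default 0.
#' @param N number of Monte-Carlo replicates; default 1e5.
#' @param seed master seed for the scenario.
#' @param window width of the conditioning window on the z scale for
#'   stratified estimates; default 0.25.
#' @return an object of class \code{"scenario_spec"}.
#' @examples
#' scenario_spec(K = 2, rho = 0.5, N = 1000, seed = 1)
#' @export
scenario_spec <- function(K = 2L, pi = 0.5, rho = 0, mu = 2, r = 0,
                          N = 1e5, seed = 1L, window = 0.25) {
  K <- as.integer(K)
  N <- as.integer(N)
  if (N < 1L) stop("N must be at least 1")
  if (!is.finite(window) || window <= 0) stop("window width must be > 0")
  prior <- common_cause_prior(pi, rho, K)           # validates pi, rho
  R <- if (r != 0) equicorrelation(K, r) else NULL  # validates r
  model <- evidence_model(K, scale = "z", mu = mu, R = R)
  structure(list(K = K, pi = pi, rho = rho, mu = mu, r = r, N = N,
                 seed = as.integer(seed), window = window,
                 prior = prior, model = model),
            class = "scenario_spec")
}

# N draws of theta from a joint prior, as an N x K 0/1 matrix
.simulate_truth <- function(prior, N) {
  if (inherits(prior, "common_cause_prior")) {
    K <- prior$K
    iid <- matrix(stats::rbinom(N * K, 1L, prior$pi), nrow = N)
    if (prior$rho > 0) {
      shared <- stats::runif(N) < prior$rho
      b <- stats::rbinom(N, 1L, prior$pi)
      iid[shared, ] <- b[shared]
    }
    iid
  } else if (inherits(prior, "independent_prior")) {
    vapply(prior$pi, function(p) stats::rbinom(N, 1L, p), numeric(N)) |>
      matrix(nrow = N)
  } else {
    tab <- prior_table(prior)
    idx <- sample.int(nrow(tab$configs), N, replace = TRUE, prob = tab$prob)
    tab$configs[idx, , drop = FALSE]
  }
}

# N draws of X given an N x K truth matrix, z scale
.simulate_z <- function(model, theta) {
  N <- nrow(theta); K <- model$K
  eps <- matrix(stats::rnorm(N * K), nrow = N)
  if (!is.null(model$R)) eps <- eps %*% chol(model$R)
  theta %*% diag(model$mu, K) + eps
}

# Marginal posteriors for every row of an N x K z-matrix, by enumeration
# shared across rows (the per-configuration log-likelihood is affine in
# theta for identity R and quadratic for general R, so the N x 2^K score
# matrix is two matrix products).
.batch_marginals <- function(prior, model, X) {
  K <- prior$K
  tab <- prior_table(prior)
  configs <- tab$configs
  logprior <- ifelse(tab$prob > 0, log(tab$prob), -Inf)
  if (is.null(model$R)) {
    l0 <- stats::dnorm(X, 0, 1, log = TRUE)
    l1 <- stats::dnorm(X, rep(model$mu, each = nrow(X)), 1, log = TRUE)
    A <- (l1 - l0) %*% t(configs)              # N x 2^K
  } else {
    Rinv <- chol2inv(chol(model$R))
    D <- diag(model$mu, K)
    lin <- X %*% Rinv %*% D                    # N x K
    qf <- rowSums((configs %*% (D %*% Rinv %*% D)) * configs)
    A <- lin %*% t(configs) - 0.5 * matrix(qf, nrow(X), length(qf),
                                           byrow = TRUE)
  }
  W <- sweep(A, 2L, logprior, `+`)
  W <- W - apply(W, 1L, max)
  P <- exp(W); P <- P / rowSums(P)
  P %*% configs                                # N x K marginals
}

#' Collider simulation: association of theta_f with X_m given X_f
#'
#' Draws (theta, X) under the scenario and estimates, within narrow strata
#' of X_f, the difference in mean X_m between replicates with theta_f = 1
#' and theta_f = 0 (inverse-variance pooled across strata), plus a linear
#' partial-correlation summary.  A positive prior association (rho > 0)
#' pulls this conditional association positive through the theta_m path; a
#' positive residual correlation (r > 0) pulls it negative through the
#' collider path opened by conditioning on X_f.
#'
#' @param spec a \code{\link{scenario_spec}} with K = 2.
#' @param min_per_group smallest per-stratum group size used; default 5.
#' @return a list with \code{estimate} (pooled mean difference),
#'   \code{se}, \code{partial_cor}, \code{n_strata}, \code{n_used}, and the
#'   per-stratum table \code{strata}.
#' @examples
#' run_collider_sim(scenario_spec(rho = 0.5, N = 20000, seed = 1))
#' @export
run_collider_sim <- function(spec, min_per_group = 5L) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$K != 2L) stop("the collider simulation is defined for K = 2")
  set.seed(spec$seed)
  theta <- .simulate_truth(spec$prior, spec$N)
  X <- .simulate_z(spec$model, theta)
  xf <- X[, 1L]; xm <- X[, 2L]; tf <- theta[, 1L]
  breaks <- seq(floor(min(xf)), ceiling(max(xf)), by = spec$window)
  stratum <- findInterval(xf, breaks)
  rows <- lapply(unique(stratum), function(s) {
    in_s <- stratum == s
    n1 <- sum(tf[in_s] == 1L); n0 <- sum(tf[in_s] == 0L)
    if (n1 < min_per_group || n0 < min_per_group) return(NULL)
    m1 <- mean(xm[in_s & tf == 1L]); m0 <- mean(xm[in_s & tf == 0L])
    v <- stats::var(xm[in_s & tf == 1L]) / n1 +
         stats::var(xm[in_s & tf == 0L]) / n0
    data.frame(stratum = s, lower = breaks[s], n1 = n1, n0 = n0,
               diff = m1 - m0, var = v)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L)
    stop("no stratum of X_f contains both theta_f groups; ",
         "widen the conditioning window or increase N")
  w <- 1 / rows$var
  est <- sum(w * rows$diff) / sum(w)
  se <- sqrt(1 / sum(w))
  # linear partial correlation of theta_f and X_m given X_f
  r_tm <- stats::cor(tf, xm); r_tf <- stats::cor(tf, xf)
  r_fm <- stats::cor(xf, xm)
  pcor <- (r_tm - r_tf * r_fm) / sqrt((1 - r_tf^2) * (1 - r_fm^2))
  list(estimate = est, se = se, partial_cor = pcor,
       n_strata = nrow(rows), n_used = sum(rows$n1 + rows$n0),
       strata = rows, seed = spec$seed)
}

#' Selection simulation: data fishing and the posterior
#'
#' The selection rule S reports the test with the larger marginal posterior
#' (ties toward the first test).  The simulation reports (a) the
#' calibration of the selected posterior -- among replicates where the
#' selected test's posterior falls in a bin, the empirical frequency of its
#' alternative being true -- and (b) the distribution of the selected
#' test's two-sided p-value among replicates where its null is true, with a
#' Kolmogorov-Smirnov distance from uniform.  Selection never enters the
#' posterior computation: the reported posterior is the same function of
#' (X_f, X_m) whether or not selection happened.
#'
#' @param spec a \code{\link{scenario_spec}} with K = 2.
#' @param bin_width calibration bin width on the posterior scale;
#'   default 0.05.
#' @return a list with \code{calibration} (per-bin table: n, mean
#'   posterior, empirical frequency, binomial SE), \code{ks} (statistic,
#'   p-value, n, and the 0.01-level critical value), and \code{n_selected_f}.
#' @export
run_selection_sim <- function(spec, bin_width = 0.05) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$K != 2L) stop("the selection simulation is defined for K = 2")
  set.seed(spec$seed)
  theta <- .simulate_truth(spec$prior, spec$N)
  X <- .simulate_z(spec$model, theta)
  marg <- .batch_marginals(spec$prior, spec$model, X)
  if (spec$N == 1L)
    warning("N = 1: the selection report is degenerate")
  sel_f <- marg[, 1L] >= marg[, 2L]        # ties broken toward test f
  sel <- ifelse(sel_f, 1L, 2L)
  idx <- cbind(seq_len(spec$N), sel)
  q_sel <- marg[idx]
  t_sel <- theta[idx]
  n_bins <- as.integer(round(1 / bin_width))
  bins <- pmin(floor(q_sel / bin_width), n_bins - 1L)
  calib <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    in_b <- bins == b
    n <- sum(in_b)
    emp <- mean(t_sel[in_b])
    data.frame(bin_lower = b * bin_width, bin_upper = (b + 1) * bin_width,
               n = n, mean_posterior = mean(q_sel[in_b]),
               empirical_freq = emp,
               se = sqrt(max(emp * (1 - emp), 1e-12) / n))
  }))
  null_sel_f <- !t_sel & sel_f
  if (!any(sel_f)) stop("no replicate selected test f; increase N")
  p_null <- z_to_p(X[null_sel_f, 1L])
  ks <- if (sum(null_sel_f) >= 2L)
    stats::ks.test(p_null, "punif") else NULL
  n_ks <- sum(null_sel_f)
  list(calibration = calib,
       ks = list(statistic = if (!is.null(ks)) unname(ks$statistic) else NA_real_,
                 p_value = if (!is.null(ks)) ks$p.value else NA_real_,
                 n = n_ks,
                 critical_0.01 = 1.62762 / sqrt(max(n_ks, 1L))),
       n_selected_f = sum(sel_f), seed = spec$seed)
}

#' Operating characteristics of posterior thresholding vs p-value rules
#'
#' Simulates truth and evidence, then applies (i) the posterior threshold
#' rule at \code{tau} using the analyst's prior from \code{spec}, (ii)
#' unadjusted p < alpha, (iii) Bonferroni, (iv) Holm, (v) BH, and reports
#' family-wise error rate, average per-test power, and FDR with MC
#' standard errors.  Setting \code{truth_pi} (e.g. 0 for the all-null
#' configuration) decouples the generating truth from the analyst's prior,
#' which keeps its stated \code{pi}.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param tau posterior decision threshold; default 0.5.
#' @param alpha significance / FDR level for the frequentist rules;
#'   default 0.05.
#' @param truth_pi optional alternative probability used to draw the truth;
#'   default: the analyst's \code{spec$pi} (self-consistent Bayes).
#' @return a data.frame, one row per method, with columns \code{method},
#'   \code{fwer}, \code{fwer_se}, \code{power}, \code{power_se},
#'   \code{fdr}, \code{fdr_se}.
#' @export
run_operating_characteristics <- function(spec, tau = 0.5, alpha = 0.05,
                                          truth_pi = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  truth_prior <- if (is.null(truth_pi)) spec$prior else
    common_cause_prior(truth_pi, spec$rho, spec$K)
  theta <- .simulate_truth(truth_prior, spec$N)
  X <- .simulate_z(spec$model, theta)
  marg <- .batch_marginals(spec$prior, spec$model, X)
  P <- z_to_p(X)
  rej <- list(
    posterior  = marg > tau,
    unadjusted = P <= alpha,
    bonferroni = pmin(spec$K * P, 1) <= alpha,
    holm       = t(apply(P, 1L, function(p) stats::p.adjust(p, "holm"))) <= alpha,
    bh         = t(apply(P, 1L, function(p) stats::p.adjust(p, "BH"))) <= alpha)
  if (spec$K == 1L) rej <- lapply(rej, function(m) matrix(m, ncol = 1L))
  nulls <- theta == 0L
  alts <- theta == 1L
  out <- do.call(rbind, lapply(names(rej), function(nm) {
    R <- rej[[nm]]
    false_any <- rowSums(R & nulls) > 0L
    fwer <- mean(false_any)
    n_alt <- sum(alts)
    pow <- if (n_alt > 0) mean(R[alts]) else NA_real_
    vr <- rowSums(R & nulls) / pmax(rowSums(R), 1L)
    data.frame(method = nm,
               fwer = fwer, fwer_se = sqrt(fwer * (1 - fwer) / nrow(R)),
               power = pow,
               power_se = if (n_alt > 0) sqrt(pow * (1 - pow) / n_alt) else NA_real_,
               fdr = mean(vr), fdr_se = stats::sd(vr) / sqrt(nrow(R)))
  }))
  attr(out, "seed") <- spec$seed
  out
}

#' Generate a synthetic evidence dataset on disk
#'
#' Draws one truth configuration and one evidence vector under the
#' scenario, writing the evidence table and a truth sidecar in the
#' package's delimited format.  Byte-identical output under a fixed seed.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param dir output directory (created if missing).
#' @param seed seed override; default \code{spec$seed}.
#' @return invisibly, a list with paths \code{evidence} and \code{truth}.
#' @export
generate_dataset <- function(spec, dir, seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop(sprintf("cannot create output directory '%s'", dir))
  set.seed(seed)
  theta <- .simulate_truth(spec$prior, 1L)
  X <- .simulate_z(spec$model, theta)
  ids <- sprintf("test_%02d", seq_len(spec$K))
  hdr <- c(sprintf("bayesmt %s", as.character(utils::packageVersion("bayesmt"))),
           sprintf("seed: %d", as.integer(seed)),
           sprintf("spec: K=%d pi=%g rho=%g mu=%g r=%g", spec$K, spec$pi,
                   spec$rho, spec$mu, spec$r))
  ev_path <- file.path(dir, "evidence.csv")
  tr_path <- file.path(dir, "truth.csv")
  write_results(ev_path, data.frame(test_id = ids, z = X[1L, ]),
                header = hdr)
  write_results(tr_path, data.frame(test_id = ids, theta = theta[1L, ]),
                header = hdr)
  invisible(list(evidence = ev_path, truth = tr_path))
}
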