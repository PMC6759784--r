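# Exact posterior inference over hypothesis configurations by full
# enumeration of {0,1}^K, in log space.
#
# joint posterior:  p(theta | X) = p(X | theta) p(theta) / sum over theta'
# marginal:         p(theta_j = 1 | X) = sum of joint mass with bit j = 1
#
# When the prior factorizes across tests AND the residual correlation is
# the identity, the marginal for test j reduces exactly to the single-test
# posterior p(theta_j = 1 | X_j): other tests' data are then irrelevant.
# The engine takes that reduction literally (the factorized path is used
# for the marginals in that case), so the reduction holds to the last bit.

.logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Exact joint posterior over hypothesis configurations
#'
#' Enumerates all 2^K configurations, scoring each by log prior mass plus
#' log likelihood, and normalizes with log-sum-exp.
#'
#' @param prior a \code{\link{joint_prior}} (see \code{independent_prior},
#'   \code{common_cause_prior}, \code{explicit_prior},
#'   \code{pairwise_prior}).
#' @param model an \code{\link{evidence_model}}.
#' @param x an \code{\link{evidence_vector}} or plain numeric vector on the
#'   model's scale.
#' @param tau optional decision threshold in (0,1); when supplied,
#'   per-test decisions \code{marginal_alt > tau} are attached.
#' @return an object of class \code{"posterior_result"}: a list with
#'   \code{configs} (2^K x K 0/1 matrix), \code{joint} (posterior mass per
#'   configuration), \code{marginal_alt} (K posterior alternative
#'   probabilities), \code{log_normalizer}, and optionally
#'   \code{decisions}.
#' @examples
#' pr <- independent_prior(c(0.5, 0.5))
#' m  <- evidence_model(K = 2, mu = 2)
#' joint_posterior(pr, m, evidence_vector(c(2, 2), "z"))
#' @export
joint_posterior <- function(prior, model, x, tau = NULL) {
  stopifnot(inherits(prior, "joint_prior"), inherits(model, "evidence_model"))
  if (!inherits(x, "evidence_vector")) x <- evidence_vector(x, model$scale)
  K <- prior$K
  if (model$K != K || x$K != K)
    stop(sprintf("dimension mismatch: prior K = %d, model K = %d, x K = %d",
                 K, model$K, x$K))
  tab <- prior_table(prior)
  ll <- .config_logliks(model, x, tab$configs)
  lp <- ifelse(tab$prob > 0, log(tab$prob), -Inf) + ll
  logZ <- .logsumexp(lp)
  if (!is.finite(logZ))
    stop("all configurations have zero unnormalized posterior mass; ",
         "the prior and the evidence are numerically incompatible")
  joint <- exp(lp - logZ)
  joint <- joint / sum(joint)
  if (.is_factorized(prior, model, x)) {
    q <- vapply(seq_len(K), function(j) {
      single_test_posterior(prior$pi[j],
                            .single_loglik(model, x, j, 0L),
                            .single_loglik(model, x, j, 1L))
    }, numeric(1))
    marginal <- q
  } else {
    marginal <- as.numeric(crossprod(tab$configs, joint))
  }
  res <- structure(list(configs = tab$configs, joint = joint,
                        marginal_alt = marginal, log_normalizer = logZ,
                        K = K),
                   class = "posterior_result")
  if (!is.null(tau)) res$decisions <- decide(res, tau)
  res
}

# independent prior + identity residual correlation + consistent scales:
# the exact factorized reduction applies
.is_factorized <- function(prior, model, x) {
  inherits(prior, "independent_prior") && is.null(model$R)
}

# log-likelihood of coordinate j alone under theta_j = t
.single_loglik <- function(model, x, j, t) {
  if (x$scale != model$scale) x <- as_z(x)
  v <- x$values[j]
  if (model$scale == "z") {
    stats::dnorm(v, mean = model$mu[j] * t, sd = 1, log = TRUE)
  } else {
    if (t == 1L) stats::dbeta(v, model$a[j], 1, log = TRUE) else 0
  }
}

# log-likelihood of x for every row of a configuration matrix, vectorized
.config_logliks <- function(model, x, configs) {
  if (x$scale != model$scale) {
    if (model$scale == "z") x <- as_z(x)
    else stop(sprintf("evidence on scale '%s' cannot be used with a '%s'-scale model",
                      x$scale, model$scale))
  }
  v <- x$values
  K <- model$K
  if (is.null(model$R)) {
    if (model$scale == "z") {
      l0 <- stats::dnorm(v, 0, 1, log = TRUE)
      l1 <- stats::dnorm(v, model$mu, 1, log = TRUE)
    } else {
      l0 <- rep(0, K)
      l1 <- stats::dbeta(v, model$a, 1, log = TRUE)
    }
    as.numeric(sum(l0) + configs %*% (l1 - l0))
  } else {
    if (x$scale != "z") stop("residual correlation requires z-scale evidence")
    # quadratic form (x - D t)' R^-1 (x - D t) expanded over all configs
    Rinv <- chol2inv(chol(model$R))
    D <- diag(model$mu, K)
    const <- drop(t(v) %*% Rinv %*% v)
    lin <- drop(D %*% Rinv %*% v)              # t . lin
    Q <- D %*% Rinv %*% D                      # t' Q t
    q <- const - 2 * as.numeric(configs %*% lin) +
      rowSums((configs %*% Q) * configs)
    logdetR <- as.numeric(determinant(model$R, logarithm = TRUE)$modulus)
    -0.5 * q - 0.5 * logdetR - 0.5 * K * log(2 * pi)
  }
}

#' Marginal posterior probability of one alternative hypothesis
#'
#' p(theta_j = 1 | X), marginalizing the joint posterior over all other
#' tests' indicators.
#'
#' @inheritParams joint_posterior
#' @param j test index.
#' @return a probability.
#' @export
marginal_posterior <- function(prior, model, x, j) {
  K <- prior$K
  j <- as.integer(j)
  if (is.na(j) || j < 1L || j > K)
    stop(sprintf("test index j = %s out of range 1..%d", j, K))
  joint_posterior(prior, model, x)$marginal_alt[j]
}

#' Single-test posterior probability of the alternative
#'
#' Bayes' rule for one test in isolation:
#' pi f1 / (pi f1 + (1 - pi) f0), computed stably in log space.  For an
#' independent prior and independent data this equals the marginal
#' posterior from the full joint analysis -- other tests are irrelevant.
#'
#' @param pi prior alternative probability in [0,1].
#' @param f0_loglik,f1_loglik log densities of the observed statistic under
#'   the null and the alternative.
#' @return p(theta = 1 | x).
#' @examples
#' single_test_posterior(0.5, dnorm(2, 0, 1, log = TRUE),
#'                            dnorm(2, 2, 1, log = TRUE))  # 0.8808
#' @export
single_test_posterior <- function(pi, f0_loglik, f1_loglik) {
  if (any(pi < 0) || any(pi > 1)) stop("pi must lie in [0,1]")
  out <- ifelse(pi == 0, 0,
         ifelse(pi == 1, 1,
                stats::plogis(log(pi) - log(1 - pi) + f1_loglik - f0_loglik)))
  out
}

#' Threshold the marginal posteriors into decisions
#'
#' Declares the alternative for test j exactly when
#' \code{marginal_alt[j] > tau} (strict: a posterior equal to tau retains
#' the null).
#'
#' @param result a \code{posterior_result}.
#' @param tau threshold in (0,1); default 0.5, i.e. "the alternative is
#'   more probable than the null".
#' @return logical vector of length K.
#' @export
decide <- function(result, tau = 0.5) {
  stopifnot(inherits(result, "posterior_result"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("tau must be a single number in (0, 1)")
  result$marginal_alt > tau
}

#' @export
print.posterior_result <- function(x, ...) {
  cat(sprintf("Exact posterior over %d tests (%d configurations)\n",
              x$K, nrow(x$configs)))
  cat("marginal P(theta_j = 1 | X):\n")
  print(round(x$marginal_alt, 4))
  if (!is.null(x$decisions)) {
    cat("decisions:\n"); print(x$decisions)
  }
  invisible(x)
}
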