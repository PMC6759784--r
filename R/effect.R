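# Conjugate Gaussian shrinkage for correlated continuous effects.
#
# theta ~ N(m0, T),  x | theta ~ N(theta, S)
#   posterior mean = m0 + T (T + S)^-1 (x - m0)
#   posterior cov  = T - T (T + S)^-1 T
#
# A priori correlation in T makes the posterior for one effect borrow
# strength from the other effects' estimates: the estimation-paradigm
# analogue of the hypothesis-indicator machinery.  Operates on the
# log-ratio (e.g. log hazard ratio) scale with S supplied, typically from
# published CIs via se_from_ci().

#' Gaussian effect model
#'
#' @param prior_mean K-vector of prior effect means (log-ratio scale).
#' @param prior_cov K x K prior covariance T (symmetric positive
#'   semidefinite).
#' @param sampling_cov K x K covariance S of the observed estimates given
#'   the true effects; T + S must be positive definite.
#' @return an object of class \code{"gaussian_effect_model"}.
#' @examples
#' gaussian_effect_model(c(0, 0), matrix(c(1, .5, .5, 1), 2), diag(2))
#' @export
gaussian_effect_model <- function(prior_mean, prior_cov, sampling_cov) {
  prior_mean <- as.numeric(prior_mean)
  K <- length(prior_mean)
  T_ <- as.matrix(prior_cov); S_ <- as.matrix(sampling_cov)
  for (nm in c("prior_cov", "sampling_cov")) {
    M <- if (nm == "prior_cov") T_ else S_
    if (nrow(M) != K || ncol(M) != K)
      stop(sprintf("%s must be %d x %d", nm, K, K))
    if (max(abs(M - t(M))) > 1e-10) stop(sprintf("%s must be symmetric", nm))
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop(sprintf("%s must be positive semidefinite", nm))
  }
  if (min(eigen(T_ + S_, symmetric = TRUE, only.values = TRUE)$values) <= 1e-12)
    stop("prior_cov + sampling_cov must be positive definite")
  structure(list(prior_mean = prior_mean, T = T_, S = S_, K = K),
            class = "gaussian_effect_model")
}

#' Conjugate posterior for correlated Gaussian effects
#'
#' @param model a \code{\link{gaussian_effect_model}}.
#' @param x K observed effect estimates.
#' @return a list with \code{mean} (posterior mean, also the mode) and
#'   \code{cov} (posterior covariance).
#' @examples
#' m <- gaussian_effect_model(c(0, 0), matrix(c(1, .5, .5, 1), 2), diag(2))
#' conjugate_posterior(m, c(1, 0))$mean  # (0.4667, 0.1333)
#' @export
conjugate_posterior <- function(model, x) {
  stopifnot(inherits(model, "gaussian_effect_model"))
  x <- as.numeric(x)
  if (length(x) != model$K)
    stop(sprintf("x has length %d but the model is %d-dimensional",
                 length(x), model$K))
  W <- .shrinkage_weights(model)
  mean_post <- model$prior_mean + drop(W %*% (x - model$prior_mean))
  cov_post <- model$T - W %*% model$T
  cov_post <- (cov_post + t(cov_post)) / 2
  list(mean = mean_post, cov = cov_post)
}

.shrinkage_weights <- function(model) {
  model$T %*% solve(model$T + model$S)
}

#' Shrinkage weight report
#'
#' The rows of T (T + S)^-1: entry (j, k) is the weight of observation
#' x_k in the posterior mean of effect j.  Off-diagonal entries quantify
#' cross-test borrowing; they vanish exactly when the prior carries no
#' correlation.
#'
#' @inheritParams conjugate_posterior
#' @return a list with \code{weights} (K x K matrix) and
#'   \code{posterior_mean}.
#' @export
shrinkage_report <- function(model, x) {
  stopifnot(inherits(model, "gaussian_effect_model"))
  W <- .shrinkage_weights(model)
  post <- conjugate_posterior(model, x)
  list(weights = W, posterior_mean = post$mean)
}
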