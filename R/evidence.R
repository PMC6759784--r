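# Evidence models p(X | theta): per-test sampling distributions of the
# observed statistics under null and alternative, with optional residual
# dependence across tests given theta (the X--X arrow of the dependent-data
# setting, e.g. the same subjects analyzed several times).

#' Construct an evidence vector
#'
#' The observed statistics, one per test, on one of three scales:
#' \code{"z"} (signed z-statistics), \code{"p"} (two-sided p-values in
#' (0,1]), or \code{"log_ratio_with_se"} (log of a ratio estimate, e.g. a
#' log hazard ratio, with its standard error).
#'
#' @param values K real numbers.
#' @param scale one of \code{"z"}, \code{"p"}, \code{"log_ratio_with_se"}.
#' @param se K strictly positive standard errors; required for
#'   \code{log_ratio_with_se}.
#' @return an object of class \code{"evidence_vector"}.
#' @examples
#' evidence_vector(c(2.06, -0.43), scale = "z")
#' @export
evidence_vector <- function(values, scale = c("z", "p", "log_ratio_with_se"),
                            se = NULL) {
  scale <- match.arg(scale)
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values)))
    stop("values must be a nonempty finite numeric vector")
  if (scale == "p" && (any(values <= 0) || any(values > 1)))
    stop("p-scale values must lie in (0, 1]")
  if (scale == "log_ratio_with_se") {
    if (is.null(se)) stop("se is required for scale 'log_ratio_with_se'")
    se <- as.numeric(se)
    if (length(se) != length(values) || any(!is.finite(se)) || any(se <= 0))
      stop("se must be strictly positive and match values in length")
  } else if (!is.null(se)) {
    se <- as.numeric(se)
    if (any(se <= 0)) stop("se, when present, must be strictly positive")
  }
  structure(list(values = values, scale = scale, se = se,
                 K = length(values)),
            class = "evidence_vector")
}

#' Convert an evidence vector to the z scale
#'
#' p-values map through the two-sided normal quantile (sign information is
#' not recoverable; the z is nonnegative); log-ratio estimates map to
#' value/se.
#'
#' @param x an \code{evidence_vector}.
#' @return an \code{evidence_vector} on the z scale.
#' @export
as_z <- function(x) {
  stopifnot(inherits(x, "evidence_vector"))
  switch(x$scale,
         z = x,
         p = evidence_vector(p_to_z(x$values), scale = "z"),
         log_ratio_with_se = evidence_vector(x$values / x$se, scale = "z"))
}

#' Construct an evidence model
#'
#' On the z scale the statistic for test j is N(\code{mu[j]}, 1) under the
#' alternative and N(0, 1) under the null (a shift-only alternative with
#' unit variance).  On the p scale it is Beta(\code{a[j]}, 1) -- density
#' a x^(a-1), concentrating near 0 -- under the alternative and Uniform(0,1)
#' under the null.  Residual dependence between tests given theta is
#' supported on the z scale only, as a Gaussian correlation matrix R;
#' combining p-scale margins with R != identity is rejected rather than
#' silently approximated.
#'
#' @param K number of tests.
#' @param scale \code{"z"} or \code{"p"}.
#' @param mu alternative mean shift(s) on the z scale; scalar or length K.
#'   Default 2.
#' @param a alternative Beta exponent(s) in (0,1) on the p scale; scalar or
#'   length K.  Default 0.1.
#' @param R K x K residual correlation matrix (symmetric, unit diagonal,
#'   positive definite), or NULL for the identity.
#' @return an object of class \code{"evidence_model"}.
#' @examples
#' evidence_model(K = 2, mu = 2)
#' evidence_model(K = 2, R = equicorrelation(2, 0.8))
#' @export
evidence_model <- function(K, scale = c("z", "p"), mu = 2, a = 0.1, R = NULL) {
  scale <- match.arg(scale)
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  mu <- rep_len(as.numeric(mu), K)
  a <- rep_len(as.numeric(a), K)
  if (scale == "p" && (any(a <= 0) || any(a >= 1)))
    stop("p-scale alternative exponent a must lie in (0, 1)")
  if (!is.null(R)) {
    R <- as.matrix(R)
    if (scale == "p")
      stop("residual correlation is supported on the z scale only; ",
           "p-scale margins with R != identity are not")
    if (nrow(R) != K || ncol(R) != K) stop("R must be K x K")
    if (max(abs(R - t(R))) > 1e-10) stop("R must be symmetric")
    if (max(abs(diag(R) - 1)) > 1e-10) stop("R must have unit diagonal")
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) stop("R must be positive definite")
    if (max(abs(R - diag(K))) < 1e-15) R <- NULL  # identity: drop
  }
  structure(list(K = K, scale = scale, mu = mu, a = a, R = R),
            class = "evidence_model")
}

#' Equicorrelation matrix
#'
#' @param K dimension.
#' @param r common off-diagonal correlation; must exceed -1/(K-1) for
#'   positive definiteness.
#' @return a K x K correlation matrix.
#' @export
equicorrelation <- function(K, r) {
  if (K > 1 && (r <= -1 / (K - 1) || r >= 1))
    stop(sprintf("equicorrelation requires r in (-1/(K-1), 1) = (%.4f, 1)",
                 -1 / (K - 1)))
  m <- matrix(r, K, K); diag(m) <- 1
  m
}

# log density of N(mean, R) at x, via the Cholesky factor of R
.dmvnorm_log <- function(x, mean, R_chol) {
  z <- backsolve(R_chol, x - mean, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(R_chol))) - 0.5 * length(x) * log(2 * pi)
}

#' Log-likelihood of the evidence given a hypothesis configuration
#'
#' With identity residual correlation the joint density factorizes into the
#' product of per-test null/alternative densities; with a general R it is a
#' multivariate normal with mean \code{mu * theta} and covariance R.
#'
#' @param model an \code{evidence_model}.
#' @param x an \code{evidence_vector} (z scale required when R is present)
#'   or a plain numeric vector interpreted on the model's scale.
#' @param config a hypothesis configuration.
#' @return the log joint density of x given theta = config.
#' @examples
#' m <- evidence_model(K = 1, mu = 2)
#' loglik(m, evidence_vector(0, "z"), hypothesis_config(0))  # log dnorm(0)
#' @export
loglik <- function(model, x, config) {
  stopifnot(inherits(model, "evidence_model"))
  if (!inherits(x, "evidence_vector")) x <- evidence_vector(x, model$scale)
  config <- hypothesis_config(config)
  if (x$K != model$K || length(config) != model$K)
    stop(sprintf("dimension mismatch: model K = %d, x K = %d, config K = %d",
                 model$K, x$K, length(config)))
  if (!is.null(model$R) && x$scale != "z")
    stop("residual correlation requires z-scale evidence; p-scale input ",
         "with R != identity is rejected rather than silently converted")
  if (x$scale != model$scale) {
    if (model$scale == "z") x <- as_z(x)
    else stop(sprintf("evidence on scale '%s' cannot be used with a '%s'-scale model",
                      x$scale, model$scale))
  }
  v <- x$values
  if (is.null(model$R)) {
    if (model$scale == "z") {
      sum(stats::dnorm(v, mean = model$mu * config, sd = 1, log = TRUE))
    } else {
      # Beta(a,1) under the alternative, Uniform(0,1) under the null
      sum(ifelse(config == 1L,
                 stats::dbeta(v, model$a, 1, log = TRUE), 0))
    }
  } else {
    if (x$scale != "z")
      stop("residual correlation requires z-scale evidence")
    .dmvnorm_log(v, model$mu * config, chol(model$R))
  }
}

#' Simulate evidence from the model
#'
#' Draws from the same joint law that \code{\link{loglik}} evaluates.
#'
#' @param model an \code{evidence_model}.
#' @param config a hypothesis configuration.
#' @param n number of draws.
#' @param seed optional integer seed for reproducibility; when NULL the
#'   caller's RNG stream is used.
#' @return an n x K numeric matrix of draws (n = 1 still a matrix).
#' @examples
#' simulate_evidence(evidence_model(K = 2), hypothesis_config(c(1, 0)),
#'                   n = 3, seed = 1)
#' @export
simulate_evidence <- function(model, config, n = 1L, seed = NULL) {
  stopifnot(inherits(model, "evidence_model"))
  config <- hypothesis_config(config)
  if (length(config) != model$K) stop("config length must equal model K")
  if (!is.null(seed)) set.seed(seed)
  K <- model$K
  if (model$scale == "p") {
    draws <- matrix(stats::runif(n * K), nrow = n)
    alt <- which(config == 1L)
    for (j in alt)  # inverse-CDF of Beta(a,1): u^(1/a)
      draws[, j] <- draws[, j]^(1 / model$a[j])
    return(draws)
  }
  mean_vec <- model$mu * config
  if (is.null(model$R)) {
    sweep(matrix(stats::rnorm(n * K), nrow = n), 2L, mean_vec, `+`)
  } else {
    d <- MASS::mvrnorm(n, mu = mean_vec, Sigma = model$R)
    if (n == 1L) d <- matrix(d, nrow = 1L)
    d
  }
}

#' Two-sided p-value / z-statistic conversions
#'
#' \code{p_to_z} maps a two-sided p-value to the nonnegative z with
#' p = 2(1 - Phi(z)); \code{z_to_p} is its inverse on z >= 0 and uses |z|
#' otherwise.
#'
#' @param p two-sided p-value(s) in (0, 1].
#' @param z z-statistic(s).
#' @return nonnegative z, or p in (0, 1].
#' @examples
#' p_to_z(0.05)          # 1.959964
#' z_to_p(p_to_z(0.04))  # 0.04
#' @export
p_to_z <- function(p) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  stats::qnorm(p / 2, lower.tail = FALSE)
}

#' @rdname p_to_z
#' @export
z_to_p <- function(z) 2 * stats::pnorm(abs(z), lower.tail = FALSE)
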