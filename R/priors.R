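# Joint priors over binary hypothesis-indicator vectors theta in {0,1}^K.
#
# The joint prior p(theta) is where an a priori association between
# hypotheses lives: dependence here is the channel through which one test's
# data inform another test's hypothesis.

# Hard cap on full enumeration: 2^20 configurations.
.K_MAX <- 20L

#' Validate a hypothesis configuration
#'
#' A hypothesis configuration is an ordered vector of K values in \{0,1\},
#' one per test: 1 means the alternative holds for that test, 0 the null.
#'
#' @param bits integer or numeric vector with entries 0 or 1.
#' @return the configuration as an integer vector, invisibly classed
#'   \code{"hypothesis_config"}.
#' @examples
#' hypothesis_config(c(1, 0))
#' @export
hypothesis_config <- function(bits) {
  if (length(bits) < 1L)
    stop("a hypothesis configuration needs at least one test (K >= 1)")
  if (!all(bits %in% c(0, 1)))
    stop("every element of a hypothesis configuration must be exactly 0 or 1")
  structure(as.integer(bits), class = "hypothesis_config")
}

.check_pi <- function(pi, what = "pi") {
  if (any(!is.finite(pi)) || any(pi < 0) || any(pi > 1))
    stop(sprintf("%s must lie in [0,1]", what))
  pi
}

#' Independent prior over hypothesis indicators
#'
#' Each indicator is an independent Bernoulli(\code{pi[j]}).  Under this
#' prior (and independent data) the posterior for one test never depends on
#' another test's data: the regime in which multiplicity adjustment is
#' irrelevant.
#'
#' @param pi vector of per-test prior alternative probabilities in [0,1].
#' @return an object of class \code{c("independent_prior", "joint_prior")}.
#' @examples
#' independent_prior(c(0.1, 0.9))
#' @export
independent_prior <- function(pi) {
  .check_pi(pi)
  structure(list(pi = as.numeric(pi), K = length(pi)),
            class = c("independent_prior", "joint_prior"))
}

#' Common-cause exchangeable prior
#'
#' With probability \code{rho} all K indicators copy a single shared
#' Bernoulli(\code{pi}) draw; otherwise they are i.i.d. Bernoulli(\code{pi}).
#' This mixture keeps every marginal at \code{pi} exactly and gives every
#' pair of indicators Pearson correlation exactly \code{rho}, spanning
#' independence (\code{rho = 0}) to a single pooled hypothesis
#' (\code{rho = 1}).  It cannot express negative association; use
#' \code{\link{pairwise_prior}} or \code{\link{explicit_prior}} for that.
#'
#' @param pi shared prior alternative probability in [0,1].
#' @param rho association weight in [0,1].
#' @param K number of tests.
#' @return an object of class \code{c("common_cause_prior", "joint_prior")}.
#' @examples
#' common_cause_prior(pi = 0.5, rho = 0.5, K = 2)
#' @export
common_cause_prior <- function(pi, rho, K) {
  stopifnot(length(pi) == 1L, length(rho) == 1L)
  .check_pi(pi)
  if (!is.finite(rho) || rho < 0 || rho > 1)
    stop("rho must lie in [0,1]; negative prior association requires ",
         "pairwise_prior or explicit_prior")
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  structure(list(pi = pi, rho = rho, K = K),
            class = c("common_cause_prior", "joint_prior"))
}

#' Explicit tabulated prior
#'
#' The joint prior given directly as one probability per configuration.
#'
#' @param mass named numeric vector; names are bitstrings such as
#'   \code{"01"}, values the prior mass of each configuration.  All 2^K
#'   configurations must be present (K inferred from the name length), the
#'   masses nonnegative and summing to 1 within 1e-12.
#' @return an object of class \code{c("explicit_prior", "joint_prior")}.
#' @examples
#' explicit_prior(c("00" = 0.5, "01" = 0, "10" = 0, "11" = 0.5))
#' @export
explicit_prior <- function(mass) {
  if (is.null(names(mass)) || any(!nzchar(names(mass))))
    stop("mass must be a named vector with bitstring names")
  K <- nchar(names(mass)[1])
  if (any(nchar(names(mass)) != K) || !all(grepl("^[01]+$", names(mass))))
    stop("names of mass must all be bitstrings of equal length")
  if (K > .K_MAX)
    stop(sprintf("K = %d exceeds the enumeration limit K <= %d", K, .K_MAX))
  want <- apply(.config_matrix(K), 1L, paste, collapse = "")
  if (length(mass) != 2^K || !setequal(names(mass), want))
    stop(sprintf("mass must contain all %d configurations exactly once", 2^K))
  if (any(mass < 0)) stop("prior masses must be nonnegative")
  s <- sum(mass)
  if (abs(s - 1) > 1e-12)
    stop(sprintf("prior masses must sum to 1 (got %.15g)", s))
  structure(list(mass = mass[want], K = as.integer(K)),
            class = c("explicit_prior", "joint_prior"))
}

#' Pairwise prior for two tests with given correlation
#'
#' A bivariate Bernoulli prior parameterized by the two marginal alternative
#' probabilities and their Pearson correlation, which may be negative.  The
#' implied 2x2 table must have nonnegative cells (Frechet bounds); requests
#' outside those bounds are rejected.
#'
#' @param pi_f,pi_m marginal alternative probabilities in [0,1].
#' @param rho Pearson correlation of the two indicators in [-1,1].
#' @return an object of class
#'   \code{c("pairwise_prior", "explicit_prior", "joint_prior")}.
#' @examples
#' pairwise_prior(0.5, 0.5, 0.5)
#' @export
pairwise_prior <- function(pi_f, pi_m, rho) {
  .check_pi(pi_f, "pi_f"); .check_pi(pi_m, "pi_m")
  if (!is.finite(rho) || abs(rho) > 1) stop("rho must lie in [-1,1]")
  p11 <- pi_f * pi_m + rho * sqrt(pi_f * (1 - pi_f) * pi_m * (1 - pi_m))
  p10 <- pi_f - p11
  p01 <- pi_m - p11
  p00 <- 1 - p11 - p10 - p01
  cells <- c("00" = p00, "01" = p01, "10" = p10, "11" = p11)
  if (any(cells < -1e-12))
    stop(sprintf(paste0("(pi_f=%g, pi_m=%g, rho=%g) violates the Frechet ",
                        "bounds: implied joint table has a negative cell"),
                 pi_f, pi_m, rho))
  out <- explicit_prior(pmax(cells, 0) / sum(pmax(cells, 0)))
  class(out) <- c("pairwise_prior", class(out))
  out$pi_f <- pi_f; out$pi_m <- pi_m; out$rho <- rho
  out
}

# All 2^K configurations as a matrix, row r = binary expansion of r-1,
# bit 1 (column 1) most significant so rows sort as bitstrings.
.config_matrix <- function(K) {
  if (K > .K_MAX)
    stop(sprintf("K = %d exceeds the enumeration limit K <= %d", K, .K_MAX))
  n <- 2^K
  m <- matrix(0L, nrow = n, ncol = K)
  for (j in seq_len(K))
    m[, j] <- bitwAnd(seq_len(n) - 1L, bitwShiftL(1L, K - j)) > 0L
  storage.mode(m) <- "integer"
  m
}

.check_config <- function(prior, config) {
  config <- hypothesis_config(config)
  if (length(config) != prior$K)
    stop(sprintf("configuration has length %d but the prior is over K = %d tests",
                 length(config), prior$K))
  config
}

#' Prior mass of one configuration
#'
#' @param prior a \code{joint_prior}.
#' @param config a hypothesis configuration of matching length.
#' @return p(theta = config), a probability in [0,1].
#' @examples
#' prior_mass(common_cause_prior(0.5, 0.5, 2), c(0, 0))  # 0.375
#' @export
prior_mass <- function(prior, config) UseMethod("prior_mass")

#' @export
prior_mass.independent_prior <- function(prior, config) {
  config <- .check_config(prior, config)
  prod(ifelse(config == 1L, prior$pi, 1 - prior$pi))
}

#' @export
prior_mass.common_cause_prior <- function(prior, config) {
  config <- .check_config(prior, config)
  pi <- prior$pi; rho <- prior$rho
  shared <- if (all(config == 1L)) pi else if (all(config == 0L)) 1 - pi else 0
  iid <- prod(ifelse(config == 1L, pi, 1 - pi))
  rho * shared + (1 - rho) * iid
}

#' @export
prior_mass.explicit_prior <- function(prior, config) {
  config <- .check_config(prior, config)
  unname(prior$mass[paste(config, collapse = "")])
}

#' Materialize the full prior table
#'
#' Enumerates all 2^K configurations with their prior mass; the input to the
#' exact posterior engine.  Refuses K above the enumeration limit (20).
#'
#' @param prior a \code{joint_prior}.
#' @return a list with \code{configs} (2^K x K 0/1 matrix, rows in bitstring
#'   order) and \code{prob} (masses summing to 1), classed
#'   \code{"prior_table"}.
#' @examples
#' prior_table(independent_prior(c(0.1, 0.9)))
#' @export
prior_table <- function(prior) UseMethod("prior_table")

#' @export
prior_table.joint_prior <- function(prior) {
  configs <- .config_matrix(prior$K)
  prob <- apply(configs, 1L, function(cfg) prior_mass(prior, cfg))
  structure(list(configs = configs, prob = prob, K = prior$K),
            class = "prior_table")
}

#' @export
prior_table.independent_prior <- function(prior) {
  configs <- .config_matrix(prior$K)
  lp <- configs %*% log(ifelse(prior$pi > 0, prior$pi, 1)) +
    (1 - configs) %*% log(ifelse(prior$pi < 1, 1 - prior$pi, 1))
  prob <- as.numeric(exp(lp))
  # zero out configurations forbidden by degenerate margins
  if (any(prior$pi == 0))
    prob[configs[, prior$pi == 0, drop = FALSE] %*% rep(1, sum(prior$pi == 0)) > 0] <- 0
  if (any(prior$pi == 1))
    prob[(1 - configs[, prior$pi == 1, drop = FALSE]) %*% rep(1, sum(prior$pi == 1)) > 0] <- 0
  structure(list(configs = configs, prob = prob, K = prior$K),
            class = "prior_table")
}

#' @export
prior_table.explicit_prior <- function(prior) {
  structure(list(configs = .config_matrix(prior$K),
                 prob = unname(prior$mass), K = prior$K),
            class = "prior_table")
}

#' Pairwise prior correlation of two hypothesis indicators
#'
#' Pearson correlation of (theta_i, theta_j) computed from the materialized
#' joint table.  Undefined (error) when either margin is degenerate.
#'
#' @param prior a \code{joint_prior}.
#' @param i,j test indices.
#' @return correlation in [-1,1].
#' @examples
#' pairwise_correlation(common_cause_prior(0.3, 0.7, 2), 1, 2)  # 0.7
#' @export
pairwise_correlation <- function(prior, i, j) {
  K <- prior$K
  if (i < 1 || i > K || j < 1 || j > K) stop("test index out of range")
  tab <- prior_table(prior)
  pi_i <- sum(tab$prob[tab$configs[, i] == 1L])
  pi_j <- sum(tab$prob[tab$configs[, j] == 1L])
  if (pi_i <= 0 || pi_i >= 1 || pi_j <= 0 || pi_j >= 1)
    stop("degenerate margin: pairwise correlation is undefined when ",
         "P(theta = 1) is 0 or 1")
  e_ij <- sum(tab$prob[tab$configs[, i] == 1L & tab$configs[, j] == 1L])
  (e_ij - pi_i * pi_j) / sqrt(pi_i * (1 - pi_i) * pi_j * (1 - pi_j))
}

#' @export
print.prior_table <- function(x, ...) {
  df <- data.frame(config = apply(x$configs, 1L, paste, collapse = ""),
                   prob = x$prob)
  cat(sprintf("Joint prior table over %d tests (%d configurations)\n",
              x$K, nrow(df)))
  print(df, row.names = FALSE)
  invisible(x)
}
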