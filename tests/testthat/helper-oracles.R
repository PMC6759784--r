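# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the package's own code paths: plain-arithmetic
# enumeration (no log space), textbook step-down/step-up loops, and the
# closed-form bivariate normal density.

# Direct-sum posterior: probs over configs (rows of `configs`), likelihood
# evaluated by `lik`, a function(x, config) returning a plain density.
oracle_posterior <- function(configs, prior_prob, lik, x) {
  w <- prior_prob * apply(configs, 1L, function(cfg) lik(x, cfg))
  w <- w / sum(w)
  list(joint = w, marginal = as.numeric(crossprod(configs, w)))
}

# density of N(mean, Sigma) at x via the textbook formula (2x2 closed form
# for K = 2, generic solve() otherwise)
oracle_dmvnorm <- function(x, mean, Sigma) {
  K <- length(x)
  d <- x - mean
  exp(-0.5 * drop(t(d) %*% solve(Sigma) %*% d)) /
    sqrt((2 * pi)^K * det(Sigma))
}

# Holm step-down by the definition: order p ascending, reject while
# p_(i) <= alpha / (m - i + 1), stop at the first failure.
oracle_holm_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) reject[o[i]] <- TRUE else break
  }
  reject
}

# BH step-up by the definition: largest i with p_(i) <= i q / m; reject
# all smaller ranks.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(ok)) reject[o[seq_len(max(ok))]] <- TRUE
  reject
}

# all 2^K configurations, independent construction (expand.grid based)
oracle_configs <- function(K) {
  g <- do.call(expand.grid, rep(list(c(0L, 1L)), K))
  m <- as.matrix(g[, rev(seq_len(K)), drop = FALSE])
  dimnames(m) <- NULL
  m[order(apply(m, 1L, paste, collapse = "")), , drop = FALSE]
}
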