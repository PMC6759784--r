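---
title: "Exact posteriors for multiple testing: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact posteriors for multiple testing: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesmt)
```

## The inferential model

`bayesmt` treats a family of K tests as one inference problem. Each test j
carries a binary indicator θ_j (1 = alternative true) and an observed
statistic X_j. The joint prior p(θ) over {0,1}^K encodes everything the
analyst believes about how the hypotheses hang together before seeing
data; the evidence model p(X | θ) says how the statistics behave under
each configuration. The package computes the posterior over all 2^K
configurations exactly, by enumeration in log space, and reports the
marginal alternative probabilities p(θ_j = 1 | X).

Exactness is the point. The conclusions this machinery supports are
structural — which adjustments are irrelevant (independent tests), which
are mandatory (associated hypotheses or dependent data), and why selection
("data fishing") needs none — and those claims are only credible if the
posterior is computed without approximation error. The cost is the
enumeration cap K ≤ 20 (2^20 ≈ 10^6 configurations); beyond that the
package refuses rather than silently approximating. Families of that size
cover the stratified/subgroup analyses the package targets; genome-scale
families need different machinery (and typically different priors).

## The joint priors

Four prior families are provided:

* `independent_prior(pi)` — θ_j ~ Bernoulli(pi_j) independently. Under
  this prior (and independent data) the marginal posterior for test j is
  *exactly* the single-test posterior; the engine computes it through that
  factorized reduction, so the identity holds to the last floating-point
  bit rather than up to round-off of a 2^K sum.
* `common_cause_prior(pi, rho, K)` — with probability rho all K
  indicators copy one shared Bernoulli(pi) draw, otherwise they are i.i.d.
  This is the package's canonical exchangeable prior because its moments
  are transparent: every margin is exactly pi and every pairwise
  correlation exactly rho, spanning independence (rho = 0) to a single
  pooled hypothesis (rho = 1). The mixture cannot express negative
  association — a deliberate trade for interpretability.
* `pairwise_prior(pi_f, pi_m, rho)` — K = 2 with an arbitrary (possibly
  negative) correlation; construction fails exactly when the implied 2×2
  table has a negative cell (Fréchet bounds).
* `explicit_prior(mass)` — any table, e.g. from a hierarchical
  elicitation.

No default value of rho is endorsed. The magnitude of a priori
association is a subject-matter judgment; the package's job is to make its
consequences computable. The worked example in the README shows the
sensitivity analysis we consider good practice: sweep rho and report the
trajectory of the posterior.

## The evidence model

The statistics' sampling distributions are not dictated by the multiple
testing logic, so the package fixes a simple, overridable convention:

* z scale — X_j ~ N(0, 1) under the null, N(mu_j, 1) under the
  alternative, default mu_j = 2. The shift-only, unit-variance alternative
  keeps the dependent-data analysis interpretable: association directions
  (θ→X positive, residual X–X positive/negative) are single signed
  quantities. mu = 2 corresponds to roughly 50% power at the two-sided
  5% level, a realistic midpoint for epidemiological studies.
* p scale — X_j ~ Uniform(0,1) under the null, Beta(a_j, 1) under the
  alternative (density a x^(a−1)), default a_j = 0.1. This is the standard
  one-parameter family for "p-values concentrating near zero"; a must lie
  in (0,1).
* Residual dependence — a correlation matrix R makes X | θ multivariate
  normal with mean mu·θ and covariance R. This exists only on the z scale:
  a Gaussian copula over Beta margins would blur the sign arguments the
  collider analysis rests on, so p-scale evidence with R ≠ identity is
  rejected outright rather than approximated.

Published ratio estimates enter through the Wald reconstruction:
SE = (ln U − ln L) / (2 z_{(1+level)/2}), z = ln(est)/SE, p = 2(1 − Φ(|z|)).
We use the exact quantile 1.959964 rather than 1.96; at the 2-decimal
precision of published tables the two are indistinguishable (a tested
fact). On the packaged hazard-ratio table this reconstruction reproduces
seven of the eight published p-values exactly at two decimals and the
eighth (printed 0.22) as 0.23 — the published inputs are themselves
rounded to two decimals, so agreement beyond that is not attainable from
the printed record.

## Numerical choices

* All posterior accumulation is in log space with log-sum-exp; products of
  K densities underflow for modest K otherwise (a K = 15 test with |z| = 8
  exercises this).
* The multivariate-normal log density is evaluated via a Cholesky factor
  of R; the batch simulators exploit the fact that the per-configuration
  log-likelihood is affine (identity R) or quadratic (general R) in θ, so
  scoring N replicates against all 2^K configurations is two matrix
  products.
* Decision thresholding is strict (`marginal > tau`); a posterior exactly
  at tau retains the null. Default tau = 0.5 ("alternative more probable
  than not").
* Degenerate priors (pi ∈ {0,1}) are honored exactly: the corresponding
  configurations get zero mass and log-space handles them as −Inf, never
  NaN.

## What the simulators generate, and what they do not

The scenario generator draws θ from the common-cause prior and z-scale
statistics with optional equicorrelated residual noise. This reproduces
the three structural regimes the package exists to demonstrate:

* prior-path association only (rho > 0, r = 0): within narrow strata of
  X_f, replicates with θ_f = 1 have *higher* mean X_m;
* residual-path only (rho = 0, r > 0): the same conditional contrast is
  *negative* — the collider reversal;
* neither: the contrast is null.

The conditional contrast is estimated by windowed stratification of X_f
(default window 0.25 on the z scale, inverse-variance pooled across
strata) because the claim is per-stratum; a linear partial correlation is
reported alongside as a robustness summary. The selection simulator
implements the report-the-larger-posterior rule (ties toward the first
test — measure-zero under continuous evidence, but defined) and reports
posterior calibration among selected tests and the KS distance of
selected-null p-values from uniform. Calibration is judged against the
mean posterior within each bin, not the bin center: the empirical
frequency of θ = 1 among replicates in a bin has expectation equal to the
mean posterior there, while the bin center differs from it by an amount
set by the bin width, which has nothing to do with miscalibration.

What the generator does *not* emulate: estimated (rather than known) null
variances, t-tails, non-Gaussian dependence, composite alternatives with
heterogeneous effect sizes, or optional-stopping designs. Passing tests
therefore certify the *logic* — the reductions, the sign patterns, the
selection invariance — under the stated Gaussian conventions, not the
calibration of any particular applied analysis.

Problem sizes are chosen so the full suite runs in well under a minute per
property: 10^3 randomized cases for the bit-level independence reduction,
10^6 forward draws for the windowed Monte-Carlo check of the enumeration
posterior (window half-width 0.15, small enough that discretization bias
is dominated by the 3-binomial-SE band), 2×10^5 replicates per collider
regime across 10 seeds, 10^5 for selection, 10^4 for shrinkage recovery.

## Effect estimation

For continuous effects (log hazard ratios and the like) the same
borrowing logic runs through the conjugate Gaussian model
θ ~ N(m0, T), x | θ ~ N(θ, S), with posterior mean
m0 + T(T+S)^{-1}(x − m0). The rows of T(T+S)^{-1} are reported as
shrinkage weights: off-diagonal entries are precisely "how much of the
other stratum's estimate enters mine", zero exactly when T is diagonal.
S is meant to be assembled from published CIs via `se_from_ci`; raw-data
likelihoods (e.g. full Cox partial likelihoods) are out of scope, the
normal approximation on the log scale standing in as is customary in
meta-analysis. The prior correlation in T is exposed with no default
endorsement, for the same reason as rho above.

## Known limitations

* Enumeration caps K at 20; no variational or MCMC fallback is offered by
  design.
* The common-cause prior cannot express negative association between
  hypotheses (use `pairwise_prior`/`explicit_prior`).
* p-scale evidence cannot carry residual dependence.
* The Wald reconstruction inherits the rounding of published inputs; its
  two-decimal agreement is the most that can be claimed.
* Selection ties are broken deterministically toward the first test; with
  discrete evidence models (not provided) this choice would matter.
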