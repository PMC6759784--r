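Package: bayesmt
Title: Bayesian Multiple Testing by Exact Posterior Enumeration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact joint and marginal posterior probabilities of binary
    hypothesis indicators under a priori associated hypotheses and possibly
    dependent test statistics, computed by full enumeration of hypothesis
    configurations.  Includes post-hoc Wald p-value reconstruction from ratio
    estimates and confidence intervals, classical multiplicity adjustments
    (Bonferroni, Holm, Benjamini-Hochberg) as a contrast class, seeded
    Monte-Carlo simulators for collider-induced evidence reversal, selective
    reporting, and operating characteristics, and conjugate Gaussian shrinkage
    for correlated continuous effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
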