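Package: popdfc
Title: Population-Level Task-Based Dynamic Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-step estimation of task-based dynamic functional
    connectivity (dFC) from region-of-interest fMRI time series.
    Subject-level time-varying correlation is estimated per region pair
    and scan by a block-wise multivariate linear process bootstrap
    combined with sliding-window Pearson correlation, Fisher
    z-transformed and summarized by the pointwise median with percentile
    bands.  Population-level condition-specific dFC curves, and the
    curve of their difference, are estimated by a semiparametric
    additive mixed model with an O'Sullivan penalized-spline smooth,
    subject and nested scan random intercepts, and variance components
    estimated by restricted maximum likelihood.  Curves are summarized
    by a non-zero-coverage statistic with exact binomial proportion
    tests against design-informed nulls, a reference-condition gating
    rule, and Benjamini-Yekutieli or Bonferroni multiplicity control,
    aggregated to network-block matrices.  A synthetic-data generator
    with known time-varying correlation and the assumed random-effect
    structure supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
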