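# popdfc — population-level task-based dynamic functional connectivity

`popdfc` estimates how the association between pairs of brain-region fMRI
time series changes over the course of a task, and how that time-varying
association differs between experimental conditions, at the level of a
study population. It is aimed at researchers who have per-subject,
per-scan ROI time series (parcel-averaged BOLD signals in delimited text)
from a repeated-measures, two-condition task design, and who want
condition-specific dynamic functional connectivity (dFC) curves with
confidence bands, a principled test of where those curves differ, and
whole-brain summaries that survive multiplicity correction.

## The method

Estimation proceeds in two steps.

**Step 1 — subject-level dFC.** For one region pair and scan, the bivariate
series is split into adjacent blocks (20 TRs by default), each block is
resampled by the multivariate linear process bootstrap (MLPB) — stack the
two centered columns into a 2L-vector, estimate its banded (flat-top
tapered) covariance, whiten by its Cholesky factor, resample the whitened
coordinates i.i.d., recolor — and the resampled blocks are concatenated
into a full-length bootstrap series. Sliding-window Pearson correlation
(window w = 20 TRs, i.e. 45 s at TR = 2.25 s; a 125-TR scan yields a
105-point dFC grid) followed by the Fisher z-transform gives one bootstrap
dFC trajectory; over B = 250 replicates the subject-level estimate is the
pointwise median, with percentile bands available.

**Step 2 — population-level dFC.** The subject-level Fisher-z estimates
`dFC_ijd` (subject i, time t_j, condition d) are pooled in a semiparametric
additive mixed model

    dFC_ijd = f_d(t_j) + b_i0 + a_is0 + e_ijd

with condition curves represented by O'Sullivan penalized splines
(K = 40 spline terms on quantile knots):

    f_B(t) = b0 + b1 t + sum_k u_k z_k(t)
    f_G(t) = f_B(t) + g0 + g1 t + sum_k w_k z_k(t)
    c(t)   = f_G(t) - f_B(t)

where `u_k ~ N(0, s_u^2)` is the smooth shared by both conditions,
`w_k ~ N(0, s_w^2)` the condition-difference smooth, `b_i0` and `a_is0`
subject and nested scan random intercepts. The five variance components
are estimated by REML (the smoothing parameter is `lambda = s_e^2/s_u^2`),
and each curve gets pointwise confidence bands from the empirical-Bayes
coefficient covariance.

**Summaries and inference.** Each curve is reduced to its *non-zero
coverage* — the fraction of the dFC grid where the band excludes zero
(0.8 means the interval is entirely above or below zero for 80% of scan
time). Coverage is tested by an exact one-sided binomial test against
design-informed nulls (0.5 for condition curves in a half-on/half-off
design; 0.14 for the difference), condition-difference tests are gated on
reference-condition significance, and multiplicity is controlled by
Benjamini–Yekutieli FDR (Bonferroni and BH available). Per-pair flags can
be aggregated into network-block percentage matrices.

A synthetic-data module generates studies with known time-varying
correlation and the assumed random-effect structure, so the whole pipeline
is testable end to end without any imaging data.

## Worked example

Simulate a small two-condition study (6 subjects, 3 scans per condition,
125 TRs; the true reference-condition association is
`z_B(t) = 0.4 + 0.3 sin(2 pi t)` on the Fisher-z scale, the alternative is
constant 0.4) and run the full pipeline on its one region pair:

```r
library(popdfc)

spec  <- synthetic_spec(n_subjects = 6, n_time = 125, seed = 42)
study <- file.path(tempdir(), "study")
simulate_study(spec, study)

cfg <- pipeline_config(n_boot = 50, seed = 42)
res <- run_pipeline(file.path(study, "manifest.tsv"), cfg,
                    file.path(tempdir(), "results"), keep_fits = TRUE)
print(res$coverage, digits = 3)
```

```
  region_a region_b kind prop_nonzero prop_positive prop_negative
1       r1       r2    B        0.914         0.914         0.000
2       r1       r2    G        1.000         1.000         0.000
3       r1       r2 diff        0.876         0.390         0.486
  direction_class    p_raw p_adjusted method significant
1   positive-only 8.16e-20   8.16e-20     BY        TRUE
2   positive-only 2.47e-32   2.47e-32     BY        TRUE
3           mixed 5.97e-17   5.97e-17     BY        TRUE
```

Both condition curves are significantly non-zero over (nearly) the whole
scan — their bands sit above zero for 91% and 100% of the 105 grid points —
and the difference curve excludes zero over 88% of the scan, negative
where the sine dips above the constant and positive where it falls below
(`direction_class = "mixed"`), as the generating curves dictate. The
underlying fit is available too:

```r
print(res$fits[["r1~r2"]])
#> <dfcm_fit> 3780 obs, 105 grid points, reference 'B' vs 'G'
#>   beta0 = 0.7421, beta1 = -0.6708, gamma0 = -0.3468, gamma1 = 0.6730
#>   variance components: eps = 0.02705, u = 5.326, w = 8.959, b0 = 0.007123, a0 = 0.0162
#>   lambda = 0.0050784
```

A command-line front end with `simulate`, `subject-dfc`, `fit-population`,
`summarize` and `run-all` subcommands (flags mirror `pipeline_config()`,
including `--no-bootstrap` for the sliding-window-only variant) is
installed at:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "popdfc.R", package = "popdfc"))')" run-all \
  --manifest study/manifest.tsv --out results --seed 42
```

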