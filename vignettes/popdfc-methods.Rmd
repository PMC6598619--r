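---
title: "Methods: two-step estimation of population-level dynamic functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-step estimation of population-level dynamic functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdfc)
```

# The estimation problem

Task-based fMRI delivers, per subject and scan, a $T \times R$ matrix of
parcel-averaged BOLD signals. Static functional connectivity summarizes a
region pair by one correlation per scan; dynamic functional connectivity
(dFC) asks how that association moves over the scan, and — in a
two-condition repeated-measures design — whether the *population-level*
time courses differ between conditions. Two obstacles shape the method:
a single sliding-window correlation trajectory is noisy enough that
apparent "dynamics" arise even between independent signals, and the study
design (multiple subjects, three scans per condition per subject) induces
a correlation structure that pooling must respect.

`popdfc` addresses both with a two-step estimator: a bootstrap-stabilized
subject-level estimate, then a semiparametric additive mixed model across
subjects, scans and conditions.

# Step 1: subject-level dFC

For one pair and scan, the bivariate series $(x_t, y_t)$, $t = 1,\dots,T$,
is divided into adjacent blocks of `block_trs` time points; when $T$ is
not a multiple of the block width, the final block absorbs the remainder
(125 TRs with 20-TR blocks give 20, 20, 20, 20, 20, 25), so every block is
at least `block_trs` long and its covariance estimate stays stable.

Each block is resampled by the multivariate linear process bootstrap
(MLPB): the two centered columns are stacked column-major into a
$2L$-vector; its $2L \times 2L$ covariance is built from sample auto- and
cross-covariances, banded by a flat-top taper
($\kappa(u) = 1$ for $|u| \le 1/2$, $2(1-|u|)$ for $1/2 < |u| \le 1$, else
$0$) at bandwidth $\lceil L^{1/3} \rceil$ lags; eigenvalues are floored at
$10^{-6}$ times the largest to enforce positive definiteness; the stacked
vector is whitened by the inverse Cholesky factor, the whitened
coordinates are standardized and resampled i.i.d. with replacement
(empirically, not parametrically), recolored, and the column means
re-added. Resampled blocks are concatenated into a full-length bootstrap
series. The taper, its bandwidth and the eigenvalue floor are exposed in
`subject_dfc_config()`; the bandwidth and floor defaults are conventional
choices for banded covariance estimation, and the column-major stacking is
fixed purely so runs are reproducible — either stacking is valid.

Each bootstrap series is reduced to a correlation trajectory by a
*centered* sliding window: the correlation at grid point $t$ is computed
over the $w$ points $[t - w/2,\; t + w/2 - 1]$, for centers
$t = w/2 + 1, \dots, T - w/2$. This convention yields exactly $T - w$
grid points (125 TRs, $w = 20$: the 105-point grid $11,\dots,115$,
discarding the first and last ten scan time points). The trailing-window
convention would give $T - w + 1$ points; the centered one is adopted
because it reproduces both desired counts simultaneously. Correlations
are clipped to $1 - 10^{-6}$ in absolute value before the Fisher
z-transform $z = \mathrm{arctanh}(r)$, which is otherwise undefined at
$|r| = 1$; a window with zero variance raises an identified error rather
than propagating NaN.

Over `n_boot` replicates (default 250) the subject-level estimate is the
pointwise median of the z-transformed trajectories, with pointwise
percentile bands at `band_level` (default 0.95). Only the median is
forwarded to the population stage; the subject-level band is descriptive.
`use_bootstrap = FALSE` gives the plain sliding-window trajectory instead
(no band) — useful as a comparison variant.

**Window and block width.** Both default to 20 TRs. At TR = 2.25 s the
window spans 45 s, inside the 30–60 s range where sliding windows resolve
task-paced association changes without drowning them in estimation noise;
shorter windows are more sensitive but noisier, longer windows smooth
real dynamics away. The block width matching the window keeps the
within-block covariance estimate well-conditioned while preserving
second-order structure at the lags the window can see.

**Seeding.** One master seed; every (subject, scan, condition, pair) unit
derives its own 31-bit stream seed by a deterministic hash
(`derive_seed()`), so per-pair results do not depend on execution order
and parallel scheduling cannot change them.

# Step 2: the population model

The subject-level Fisher-z estimates are pooled as

$$\mathrm{dFC}_{ijd} = f_d(t_j) + b_{i0} + a_{is0} + \varepsilon_{ijd},$$

with subject $i$, grid time $t_j$, condition $d \in \{B, G\}$ (reference
$B$), subject intercept $b_{i0} \sim N(0, \sigma_{b0}^2)$, a nested
intercept $a_{is0} \sim N(0, \sigma_{a0}^2)$ for each of the six
(scan, condition) cells within subject, and independent
$\varepsilon_{ijd} \sim N(0, \sigma_\varepsilon^2)$. The condition curves
are

$$f_B(t) = \beta_0 + \beta_1 t + \textstyle\sum_k u_k z_k(t), \qquad
  f_G(t) = f_B(t) + \gamma_0 + \gamma_1 t + \textstyle\sum_k w_k z_k(t),$$

so the difference $c(t) = f_G(t) - f_B(t)$ has its own smooth: $u_k \sim
N(0, \sigma_u^2)$ is shared by both conditions and $w_k \sim N(0,
\sigma_w^2)$ captures the departure — the literal additive structure, with
the alternative-condition curve decomposed as shared smooth plus difference
smooth.

**Basis.** $z_k$ are O'Sullivan penalized splines: a cubic B-spline basis
on quantile knots with the integrated-squared-second-derivative penalty,
rotated to mixed-model form so the fixed part is $[1, t]$ (the penalty
null space) and the random part has an identity penalty. The penalty
matrix is computed exactly by 3-point Gauss–Legendre quadrature per
inter-knot interval (second-derivative products of cubics are quartic,
which that rule integrates exactly). `K` counts spline *terms*: $K - 2$
interior knots give a cubic basis of dimension $K + 2$, and removing the
two-dimensional null space leaves exactly $K$ penalized directions — so
the default `K = 40` produces a $J \times 40$ design on the 105-point
grid. Penalization makes results insensitive to the exact knot count:
surplus flexibility is shrunk away. Time is rescaled to $[0, 1]$ over the
dFC grid for conditioning; reported slopes are per rescaled unit.

**Estimation.** The five variance components are estimated by REML. The
restricted likelihood is profiled over $\sigma_\varepsilon^2$ and
optimized over the four log variance ratios; all objective evaluations
reuse fixed crossproducts via the Woodbury identity, so each costs a
$q \times q$ Cholesky ($q \approx 250$ at study scale). The optimizer runs
Nelder–Mead first and then a bounded quasi-Newton polish, keeping the
better optimum: the profiled surface can be nearly flat in a ratio
direction near a variance boundary, where a gradient method started at
equal variances (each component initialized at a fifth of the response
variance, i.e. all ratios 1) can overshoot to the bound and stall.
Boundary solutions are legitimate: ratios are bounded on the log scale,
a component at the bound is reported as (numerically) zero, and the
smoothing parameter $\lambda = \sigma_\varepsilon^2/\sigma_u^2$ — stored,
not re-derived — is reported as `Inf` when $\sigma_u^2$ is at zero. The
convergence tolerance is $10^{-8}$ on the objective. When data fit
exactly (an artificial but testable case) the profiled residual sum of
squares is floored to keep the objective evaluable; coefficients are then
the exact interpolants. Coefficients at the optimum solve the
mixed-model (penalized normal) equations; random effects are BLUPs;
a non-converged optimizer flags the fit and `predict_curves()` refuses
it rather than producing silently wrong bands.

**Bands.** Pointwise intervals are
$\hat f(t) \pm z_{1-(1-\text{level})/2}\,\mathrm{SE}(t)$ with standard
errors from the empirical-Bayes coefficient covariance
$\sigma_\varepsilon^2 [C^\top C + \mathrm{blockdiag}(0,
\sigma_\varepsilon^2 G^{-1})]^{-1}$ conditional on the plugged-in variance
components. Variance-component uncertainty is ignored — standard
penalized-spline practice. The identity $c(t) = f_G(t) - f_B(t)$ holds
exactly at every grid point by construction of the contrast matrices.

The static counterpart (sFCM) drops the smooth and the slope:
$z = \beta_0 + \gamma_0 d + b_{i0} + a_{is0} + \varepsilon$, fitted by the
same REML engine, reporting Wald $t = \hat\theta/\mathrm{SE}$ with
two-sided p-values from the large-sample normal reference (with 144
scan-condition cells the normal and t references are close; at much
smaller designs the normal reference is mildly liberal).

# Summaries and inference

The *non-zero coverage* of a curve is the fraction of grid points where
its band lies entirely above or entirely below zero, reported with its
signed split and a direction class (positive-only / negative-only /
mixed / none). It is tested by an exact one-sided binomial tail
$P(X \ge k)$, $X \sim \mathrm{Bin}(J, p_0)$, with $k$ the smallest count
consistent with the observed proportion ($k = \lceil \text{prop} \cdot J
\rceil$ up to a $10^{-9}$ guard — this also handles null proportions like
0.14 whose product with $J$ is not an integer). Grid points are treated
as exchangeable trials; the curve's temporal smoothness makes the test
approximate, which the output records. The design-informed nulls are 0.5
for condition curves (stimulus-on and rest periods each occupy half the scan,
and window smoothing precludes isolating the on-periods) and a less
stringent 0.14 for the difference curve (roughly one stimulus block out of
the trial sequence, adjusted for the grid's trimmed edges); both are
configurable constants. For the difference curve the positive and
negative coverages are tested separately and combined as twice the
smaller one-sided p, capped at one — a directional combination chosen
because difference results are reported in signed classes.

Across pairs, each curve family is corrected by Benjamini–Yekutieli
step-up FDR (valid under dependence; Benjamini–Hochberg and Bonferroni are
options, the latter as the family-wise-error comparison). Difference
tests are *gated*: only pairs whose reference-condition curve is
significant enter the difference family, and the family is restricted
before correction (restriction after correction is available as an
option; restricting first is the default because the gate is part of the
hypothesis, not a post-hoc filter — and a smaller family can only help the
step-up). Significance flags aggregate to network-block matrices of
percent-significant pairs.

# The synthetic-data generator

`synthetic_spec()` describes a study with the structure the population
model assumes: defaults are 24 subjects, 3 scans per condition, two
conditions, 125 TRs at TR = 2.25 s, true condition curves
$z_B(t) = 0.4 + 0.3\sin(2\pi t)$ and $z_G(t) \equiv 0.4$ on the Fisher-z
scale, and random shifts $b_i \sim N(0, 0.1^2)$,
$a_{is} \sim N(0, 0.05^2)$ acting *additively on the z scale* (so
parameter recovery is well-defined against the model being fitted),
back-transformed through $\tanh$ and clipped to $[-0.99, 0.99]$ for
generation: $x_t \sim N(0,1)$,
$y_t = \rho(t) x_t + \sqrt{1-\rho(t)^2}\, e_t$. The default curves are
band-limited so a 45 s window can resolve them; amplitudes 0.3–0.4 and
shift SDs 0.05–0.1 are in the range of plausible between-subject
connectivity variation on the z scale. `simulate_dfcm_data()` instead
draws responses directly from the population model on a dFC grid (no time
series), with residual SD $\sigma_\varepsilon = 0.2$ — the order of the
sampling noise of a 20-TR windowed Fisher-z correlation
($\approx 1/\sqrt{w-3}$) — which isolates the population stage for
calibration experiments.

What the generator does *not* emulate: autocorrelated BOLD noise, scanner
drift, motion artifacts, hemodynamic lag, or more than two regions per
file (multi-region studies are a loop over pairs). Passing tests
therefore demonstrate correctness of the estimator under its own
modeling assumptions, not robustness to fMRI noise processes the
out-of-scope preprocessing pipeline is meant to remove.

# Validation design and problem sizes

The test suite checks each computational core against an independent
oracle: pair enumeration against a brute-force double loop; the
proportion test against direct binomial-pmf enumeration; the mixed-model
solver at fixed variance components against a dense penalized
normal-equation solve; the static model against an independent `lme4`
fit; MLPB resamples against the sample second-order structure of the
input; and the sliding-window-only mode against the bootstrap mode's
per-replicate computation. Monte-Carlo experiments run at reduced sizes
chosen to keep the default suite in minutes: curve recovery on a full
24-subject study with 50 bootstrap replicates; band calibration and
null-difference control over 200 population-stage simulations with 8
subjects and a 50-point grid.

# Known limitations

* **Plug-in bands undercover slightly.** In the suite's calibration
  experiment the 95% pointwise band covers the true reference curve at
  about 91–93% on average (8 to 24 subjects), not 95%: replicates where
  REML underestimates the subject variance produce bands too narrow to
  absorb the realized mean subject shift. This is the known cost of
  ignoring variance-component uncertainty (and of the normal rather than
  a t multiplier); bands should be read accordingly with few subjects.
* The proportion test ignores temporal dependence between grid points,
  so its p-values are approximate (conservative gating and FDR under
  dependence mitigate, but do not remove, this).
* Subject-level bootstrap uncertainty is not propagated into the
  population model — only the median trajectory is, matching the
  two-step design.
* Smoothing-parameter selection is REML-only (no GCV/AIC); bands are
  pointwise, not simultaneous; responses are assumed Gaussian on the
  z scale.
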