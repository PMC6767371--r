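---
title: "One-stage meta-analysis of aggregate continuous outcomes via pseudo IPD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-stage meta-analysis of aggregate continuous outcomes via pseudo IPD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipdmeta)
```

## The problem

Meta-analyses of continuous outcomes almost always start from aggregate
data: each study reports, per arm, a group mean, a standard deviation and a
sample size. The classical two-stage approach computes a mean difference and
its variance per study and pools them with a random-effects model
(DerSimonian-Laird, REML, possibly with the Hartung-Knapp correction).
Two-stage pooling treats the within-study variances as *known* even though
they are estimates, forces one rigid variance assumption on every study, and
relies on normal-quantile intervals that are too narrow when the number of
studies is small.

If individual participant data (IPD) were available, one would instead fit a
single linear mixed model (LMM) to all outcomes — a one-stage analysis that
propagates the uncertainty in every variance estimate and lets the analyst
model within-study variances flexibly. This package makes that possible
*without* the IPD, by exploiting a property of the Gaussian likelihood: the
per-arm sample mean and SD are sufficient statistics. Any synthetic dataset
with exactly the observed per-arm means and SDs — "pseudo IPD" — has the
same likelihood as the unobserved real data, so every likelihood-based
estimate, standard error, likelihood-ratio test and information criterion is
identical.

## Pseudo IPD construction

For an arm with summary `(m, s, n)` the package offers two constructions,
both exact in their first two sample moments:

* **two_point** (default, deterministic): one observation at
  `m + s (n-1)/sqrt(n)` and `n - 1` observations at `m - s/sqrt(n)`. This is
  derived from first principles as the affine image of the seed vector
  `(1, 0, ..., 0)`; it is the unique two-point configuration with exact mean
  and exact `n-1`-denominator SD. We verified the construction by direct
  computation of the moments (it is also unit-tested that way).
* **rescale_normal**: draw `n` standard normal values `z` and return
  `m + s (z - mean(z)) / sd(z)`. Statistically equivalent, but the values
  look like a plausible sample, which is preferable if one wants residual
  diagnostics or wishes to export the pseudo data to another program.

Sufficiency means the choice (and the seed) cannot affect any reported
quantity; the test suite asserts agreement to within `1e-6` relative
tolerance across seeds and methods, and `verify_sufficiency()` checks the
moments to `1e-12`. Arms with `sd = 0` are allowed at generation (every
value equals the mean) but flagged, because they make per-arm residual
variances inestimable; the fit refuses them later with a message naming the
arm — failing late with context rather than early without.

## The model grid

With `y[ijk]` the outcome of participant `k` in arm `j` (treatment indicator
`x`) of study `i`, three effect structures of increasing generality are
available:

1. **FF** — fixed study intercepts, common fixed treatment effect
   `beta1`;
2. **FR** — fixed study intercepts, random treatment effects
   `b1_i ~ N(0, tau1^2)` around the mean effect `beta1`;
3. **RR** — random intercepts *and* random treatment effects,
   `(b0_i, b1_i)` bivariate normal with unstructured covariance `G`
   (a diagonal `G` is available as an option; the unstructured default
   follows the argument that correlation between study level and effect is
   often realistic).

crossed with four residual-variance structures: free per study-arm (`2m`
parameters), per study (`m`), per arm (2), or pooled (1). The 3 x 4 grid is
fitted by `model_grid()`; single cells by `fit_lmm()`.

## Estimation and numerical choices

The marginal likelihood of each study is Gaussian with covariance
`V_i = Z_i G Z_i' + R_i`. Because every covariate is constant within an
arm, the likelihood depends on the data only through per-arm means, sums of
squares, and counts; internally each arm is collapsed to those three
numbers (the participant-level data frame remains the public interface).
Two independent implementations of this likelihood exist in the package:
the fitting pathway uses the Woodbury/determinant-lemma collapse, while
`loglik_from_sufficient_stats()` evaluates the marginal normal density of
the per-study mean vector plus the chi-square contribution of the within-arm
deviations. Their agreement (and agreement with a brute-force dense-matrix
evaluation) is asserted at random parameter points in the tests — a
deliberate dual-route check.

Numerical decisions, made once:

* **Parameterization.** Log-variances for all `sigma^2` and `tau^2`;
  log-Cholesky factor for the unstructured 2 x 2 `G`. This makes the search
  unconstrained and keeps `G` positive semi-definite by construction.
* **Optimizer.** L-BFGS-B with numerical gradients, bounds of +/-30 on the
  log scale, a stringent-tolerance restart at the optimum (which resets the
  Hessian approximation and recovers several digits in flat directions), a
  Nelder-Mead fallback, and two starting points: per-group sample-variance
  moments with a DerSimonian-Laird-informed `tau^2`, and a pooled-variance
  start — informative starting values are the standard remedy for
  convergence trouble in these models. Relative convergence tolerance
  `1e-10`, at most 500 iterations.
* **Boundaries.** The profile likelihood is flat in a log-variance near
  zero, so an optimizer can stall just above the boundary; components
  below `1e-6` are snapped to the bound when that does not worsen the
  objective, floored at `exp(-30)` internally, and reported as 0 with a
  `boundary` flag when below `1e-8`.
* **Constants.** All `-2 log L` values include their `2*pi` constants (and
  the fixed-effects cross-product determinant for REML), so they are
  directly comparable with SAS PROC MIXED and nlme. The fixed design uses
  cell-means study dummies plus a treatment indicator, which is a
  unimodular reparameterization of the overparameterized CLASS coding SAS
  uses — the REML determinant term is therefore identical.
* **Degrees of freedom.** Wald t-intervals use an emulation of the SAS
  containment default: `m - 1` degrees of freedom for the treatment effect
  when a random treatment effect is present, residual degrees of freedom
  otherwise. This reproduces the published intervals for the worked
  examples; other df methods reportedly gave very similar results there and
  are not implemented.
* **AIC accounting.** `AIC_ML` counts fixed plus (co)variance parameters;
  `AIC_REML` counts (co)variance parameters only.

REML likelihood-ratio tests between nested residual structures are provided
by `lrt_compare()`, which refuses REML comparisons across different
fixed-effect structures (restricted likelihoods are not comparable then) —
FF and FR share a fixed part, RR does not.

## Two-stage comparators

`two_stage()` implements the classical pipeline on the same aggregate data:
per-study differences `d_i` with variances `sd1^2/n1 + sd0^2/n0`, then

* **DL** — the Q-statistic moment estimator of `tau^2` truncated at zero,
  inverse-variance pooling, normal-quantile CI;
* **REML** — Fisher scoring on the restricted likelihood of
  `d_i ~ N(mu, v_i + tau^2)` started at the DL estimate (with a direct
  golden-section maximization as a fallback when scoring cycles within
  rounding error of the optimum);
* **REML_HK** — the Hartung-Knapp variance rescaling with a `t(k-1)`
  interval; it changes only the SE/CI, never the point estimate or `tau^2`.

One deliberate deviation from a drafting note we worked from: the plain
(non-HK) REML interval here uses the normal quantile rather than `t(k-1)`,
because that is what standard software (metafor) does and what the published
comparator rows show; the `t(k-1)` construction belongs to the HK-corrected
interval, which is implemented as such. Interval conventions for the plain
REML comparator are not load-bearing for any accuracy check.

## The simulation framework and what it can establish

`run_simulation()` reproduces the design used to study coverage: data are
generated from the RR model with `theta = 3`, residual SDs 4 (treated) and
1 (control), diagonal `G = diag(4, 2)`, for `m` in {6, 12} studies and
`n` in {5, 10, 40} per arm, 500 replicates per cell. Each replicate is
reduced to aggregate summaries (exactly what a meta-analyst would see),
pseudo IPD are rebuilt, and three analyses are compared: the one-stage
RR model with arm-specific residual variances (REML, `t(m-1)` interval),
two-stage DL, and two-stage REML with HK. The analysis model fits an
unstructured `G` even though the generator uses a diagonal one — estimating
the correlation is what an analyst would do, and it is also the harder test;
a diagonal-`G` refit is the fallback when the unstructured fit fails.
Per-replicate seeds are derived from the master seed by a counter scheme,
so results are independent of execution order and each replicate is
reproducible in isolation.

The generator emulates exactly the stated world above — balanced arms,
normal outcomes, no covariates, no missingness, no publication bias. A green
coverage test therefore establishes calibration of the methods *under the
generating model*, not robustness to the many ways real meta-analyses
deviate from it. Monte-Carlo uncertainty is reported as a binomial SE and
all comparisons in the tests allow three such SEs.

## Known limitations

* No ANCOVA/baseline adjustment, no covariates or meta-regression, no
  network structures, no score-method intervals: the package covers the
  two-group contrast without covariates.
* Containment df is an emulation adequate for two-arm meta-analytic
  designs, not a general implementation; Satterthwaite/Kenward-Roger are
  out of scope.
* Missing SDs are not imputed; the aggregate table must be complete.
* With very few studies the RR model is weakly identified (a warning is
  issued below 3 studies) and between-study correlation estimates of +/-1
  do occur, as the original analyses also observed.
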