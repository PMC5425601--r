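---
title: "Comparing indirect effects between two groups: models, tests, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing indirect effects between two groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medgroup)
```

## The model and its estimands

The package works with the three-variable mediation chain X → M → Y observed
in two distinct groups. Within group *g* the structural equations are linear
with normal residuals:

- M equation: `M = int_m + a_g X + e_M`, `e_M ~ N(0, psi_M(g))`
- Y equation: `Y = int_y + b_g M + c'_g X + e_Y`, `e_Y ~ N(0, psi_Y(g))`

The *simple (conditional) indirect effect* in group *g* is the product
`a_g * b_g`; the *group difference in the indirect effect* is
`a_G1 b_G1 - a_G2 b_G2`. Because the model is recursive and Gaussian, the
maximum-likelihood coefficient estimates coincide with per-equation least
squares, and the ML information matrix is exactly block-diagonal between the
two equations and between the two (independent) groups. The package computes
those blocks from the data rather than assuming them, and its test suite
verifies the block structure against numerically differentiated Hessians.

Two parameterizations of the two-group model are provided.

**Single-group** (`fit_single_group`): one model over all observations. The M
equation gains a group dummy and an X-by-group product term, so with coding
0 = reference, 1 = focal, `a1` is the X→M effect in the reference group, `a1 +
a3` the effect in the focal group, and `a3` their difference. The Y equation
regresses Y on M and X only. This parameterization pools `b`, `c'` *and both
residual variances* across groups — the classical homogeneity-of-variance
assumption. The coding is an explicit `group_coding` object because the
interpretation of `a1` and `a3` depends on it; all output is reported per
group label, never per numeric code.

**Multi-group** (`fit_multi_group`): one model per group with free per-group
residual variances, estimated jointly. Cross-group equality constraints can
be imposed on `a`, `b`, `c'` (`a_equal`, `b_equal`, `cprime_equal`) or on the
product `a*b` (`ab_product_equal`). The unconstrained fit factorizes into
per-group least-squares fits; this is tested to 1e-8.

## Why the two parameterizations disagree slightly

With `b_equal` and `cprime_equal` imposed, the multi-group model has the same
*fixed-effect* structure as the single-group model, and the per-group `a`
estimates agree exactly (the interaction coding saturates the M equation by
group). The pooled `b` and `c'` estimates agree only approximately: the
multi-group constrained ML weights the two groups by their estimated residual
variances (and keeps per-group Y intercepts), while the single-group model
pools both. The two solutions coincide in the limit of equal sample residual
variances and vanishing intercepts, and differ in the third decimal place at
realistic sample sizes — which is also visible in published two-group
analyses that report both parameterizations. The package treats this as a
property of the models, not a numerical defect.

## Estimation details

- **Residual variances use the ML (1/n) denominator**, not the OLS 1/(n−p)
  denominator. Coefficient point estimates are unaffected; the choice makes
  `-2 log L` an exact Gaussian deviance so likelihood-ratio statistics are
  exact deviance differences. Standard errors are correspondingly ML-scaled
  (they differ from regression-table standard errors by the factor
  `sqrt((n-p)/n)`, immaterial at the sample sizes the methods target).
- **Linear equality constraints** are fitted by stacked estimation with
  shared coefficients and per-group variance weights, iterating WLS for the
  coefficients and closed-form updates for the variances (coordinate ascent
  on the likelihood). Convergence: relative change in `-2 log L` below 1e-10,
  cap of 500 iterations.
- **The product constraint** `a_G1 b_G1 = a_G2 b_G2` has no closed form. The
  package profiles the likelihood over the common product value tau: at fixed
  tau the problem separates by group, and within a group fixing `b` gives
  `a = tau/b` with closed-form intercepts and `c'`, leaving nested
  one-dimensional minimizations. The nested-profile solution is then polished
  by BFGS with an analytic gradient under the reparameterization
  `a_G2 = a_G1 b_G1 / b_G2`. The profile gives a reliable global start (it is
  itself the constrained ML up to line-search tolerance) and the polish
  sharpens it; this proved more robust than multi-start quasi-Newton alone.
  When `|b_G2|` is numerically zero the reparameterization is
  ill-conditioned and the symmetric form solving for `b_G2` is available via
  `solve_for`. Combining `ab_product_equal` with `b_equal` reduces
  algebraically to `a_equal` + `b_equal` (for shared nonzero b the products
  are equal iff the a paths are), and the package applies that reduction —
  which also yields the known identity that the LR test of equal indirect
  effects equals the LR test of equal a paths whenever b is shared.
- **Collinearity** is detected on the standardized design at condition
  number 1e10 and reported with the offending column name.

## Inference methods

For the group difference in the a path: the single-group z test
(`z_test_a3`, pooled-variance) and the multi-group 1-df LR test (`lr_test`
with `a_equal`). For the group difference in the indirect effect: the
delta-method Wald tests (`wald_product_test` on `a3*b`; `wald_diff_test` on
the difference of products), the LR test with `ab_product_equal`, and
percentile / bias-corrected bootstrap and Monte Carlo intervals. For the
simple indirect effects: bootstrap intervals under either parameterization
and Monte Carlo intervals under the multi-group one.

Numerical conventions that the literature leaves open, fixed here:

- **Quantile rule.** Interval endpoints use order statistics with outward
  rounding: lower endpoint at index `floor((B+1)·p)`, upper at
  `ceiling((B+1)·p)`, clamped to `[1, B]`. For draws 1..1000 at the 95% level
  this selects the 25th and 976th ordered values. The outward pair keeps
  symmetric draws producing symmetric endpoints (indices sum to B+1) and is
  marginally conservative — realized coverage carries a positive offset of
  roughly `2/(B+1)`, visible at B = 500, negligible at B = 1000.
- **Bias correction.** `z0 = qnorm(prop)` with `prop` the fraction of draws
  strictly below the point estimate, draws exactly equal counting half (this
  reduces bias from discrete estimates on small samples). A proportion of 0
  or 1 is clamped to `1/(2B)` (or its complement) and flagged.
- **Bootstrap resampling** is stratified by group by default, keeping both
  group sizes fixed — this matches the multi-group scheme, where groups are
  separate samples, and the fixed group sizes of the simulation design.
  Pooled resampling of the combined sample is available for the single-group
  approach. Degenerate resamples (zero X variance or singular Y design) are
  redrawn up to ten times, then dropped and counted; above 1% dropped the
  result carries a warning, above 10% it is an error.
- **Monte Carlo intervals** draw the four path estimates from independent
  normals centred at the estimates with their ML standard errors: the
  cross-group covariance is zero because the samples are independent, and
  the within-group covariance between the a and b estimates is set to zero,
  as is conventional for this method (they come from different equations, so
  the ML information is block-diagonal there anyway).
- Defaults are B = 1000 bootstrap resamples and R = 1000 Monte Carlo draws,
  both configurable; p values are two-sided for z and upper-tail for
  chi-square.

## The synthetic-data generator and the simulation engine

`population_catalog()` returns the 21 standard populations: three structural
sets (I: a = 0.424 both groups; II: a = 0 vs 0.141; III: a = 0 vs 0.424, all
with b = 0.390 and c' = 0) crossed with seven residual-variance patterns
(equal; psi_M of 0.5 vs 1/1.5/2; psi_Y of 0.5 vs 1/1.5/2). `var(X) = 1` in
every population — the value is not always stated alongside the structural
parameters, but it is the unique choice consistent with the published
explained-variance table (`0.424^2/(0.424^2+1) = 0.152`), and
`explained_variance()` reproduces that table to three decimals, which the
test suite checks for all 21 populations against large-sample empirical R².

`generate_dataset()` draws X fresh per group per replication (random-X
design; a fixed-X design is not used because row resampling in the bootstrap
treats X as random too), builds M and Y from the linear-normal equations
with zero intercepts, and is deterministic given its seed.
`run_condition()` derives per-replication seeds from the master seed through
a counter scheme, so any replication is independently reproducible and whole
conditions are reproducible bit-for-bit (tested with `identical()`).
Replications are evaluated at the standard group-size patterns (150, 150),
(200, 100), (100, 200); rejection means test p below alpha or interval
excluding zero; coverage, width, and miss sides are recorded against the
population value of the estimand. Every rate carries its binomial Monte
Carlo standard error, so reduced-replication runs have explicit tolerances.

**Miss-side orientation.** A *left-side miss* is an interval lying entirely
below the true value, a *right-side miss* one lying entirely above it, with
closed-interval coverage at the boundary. This orientation reproduces the
published pattern that intervals for a *null* simple indirect effect miss
more often on the left (ratio above 1) and those for a positive effect miss
more often on the right. The ratio is reported as left/right and flagged
undefined when there are no right-side misses.

What the generator does *not* emulate: non-normal residuals, measurement
error in X/M/Y (latent variables), more than two groups, and missing data.
Passing calibration tests therefore demonstrates correctness of the methods
under the linear-normal two-group design, not robustness beyond it.

## Problem sizes used by the test suite

The calibration checks run at sizes chosen to give informative Monte Carlo
standard errors while keeping the default suite practical: 1,000
replications for the null-calibration and bootstrap/Monte Carlo Type I
checks (MC SE about 0.007 at p = 0.05), 800 replications with paired
standard errors for the variance-heterogeneity contrasts (pairing the
per-dataset rejection indicators makes the method contrasts considerably
sharper than unpaired binomial SEs), and the full 63-condition grid at 300
replications for the coverage/width aggregates, with B = 599 bootstrap
resamples — a size at which `(B+1)·0.025` is an exact integer, so the
order-statistic endpoints sit exactly at the nominal quantiles and the
outward rule contributes no rounding offset. The acceptance script mirrors
these sizes.

A known, documented discrepancy: with the outward quantile rule the
percentile-bootstrap difference intervals are marginally conservative, so
their grid-average coverage sits near 0.95 where the published average is
0.939. The roughly one-point offset exceeds pure Monte Carlo noise; it is
consistent with the endpoint-convention sensitivity discussed above (the
original study does not state its quantile rule). The corresponding average
width agrees to within a few percent.

## Known limitations

- Exactly two groups; moderators with more levels or continuous moderators
  are out of scope.
- No latent-variable measurement models; observed variables only.
- Missing data are rejected listwise at load time.
- No robust/sandwich standard errors; inference is Gaussian ML.
- The normal-theory (Sobel-type) standard-error interval for the indirect
  effect is deliberately not provided: the sampling distribution of a
  product of coefficients is not normal at realistic sample sizes, which is
  the reason the resampling methods exist.
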