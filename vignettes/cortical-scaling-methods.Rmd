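---
title: "Models and methods behind cortiscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cortiscale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortiscale)
```

This vignette is the package's own account of the statistical machinery:
the models it fits, the assumptions they make, the defaults and why, what
the synthetic-data generator does and does not emulate, and the numerical
choices taken where the design was genuinely open.

## The scaling models

Three-dimensional objects of identical shape but different size obey
surface ∝ volume^(2/3) and thickness ∝ volume^(1/3). Real cortices do not:
bigger brains are disproportionately more folded. Folding itself, however,
follows a remarkably stable power law across mammalian species and human
ages,

> total SA · CT^0.5 = k · (exposed SA)^1.25.

`fit_scaling()` estimates the three exponents by ordinary least squares on
the log10 scale:

* `total_sa_vs_volume`: log10(total SA) ~ α·log10(supratentorial volume) + covariates
* `ct_vs_volume`: log10(CT) ~ α·log10(supratentorial volume) + covariates
* `folding`: log10(total SA · CT^0.5) ~ α·log10(exposed SA) + covariates

Assumptions: linearity on the log scale, additive Gaussian errors of
constant variance, and exchangeable subjects (each scanned once — no
longitudinal structure is modelled). The exponent estimate is a plain
regression coefficient, so its 95% CI is α ± t(0.975, df)·SE, and
`compare_alpha()` tests it against a constant (2/3, 1/3, 1.25, or a
published adult value) with a two-sided t-test, treating the reference as
known. Base-10 logarithms are used everywhere for coherence; the exponent
is invariant to the base (only intercepts move), as the test suite checks.

Default covariates are sex (female = 0, male = 1), postmenstrual age at
scan (PMA, weeks), PMA², and multiple birth (0/1); group contrasts add the
birth-weight z-score. PMA is centred before squaring so the linear and
quadratic columns are not nearly collinear; the focal exponent is exactly
invariant to that centring (tested to 12 digits). Aliased designs are
refused with the offending column named rather than silently dropped —
except in the `run_full_analysis()` orchestrator, which first removes
covariates that are *constant within the analysis subset* (multiple birth
is rare and can easily be absent from a small group; a constant column
carries no information and would otherwise abort the pipeline).

## The assumption gate and the robust fallback

Before accepting an OLS fit, `check_assumptions()` computes four
directional statistics on the residuals, each approximately χ²(1) under a
correctly specified Gaussian model:

* skewness: n·skew²/6,
* excess kurtosis: n·(kurt − 3)²/24,
* link misspecification: squared t-statistic of squared fitted values added
  to the design (a RESET-style term),
* heteroscedasticity: studentised n·R² of squared residuals regressed on
  fitted values.

Their sum is referred to χ²(4); when its p-value falls below the gate
threshold (0.05 — the conventional level; nothing in the procedure is
sensitive to mild changes) the model is refitted by `fit_fast_s()`.
Simulation in the test suite confirms the global statistic is calibrated
(≈5% trigger rate, uniform p) at n = 1000 under the null and that the
heteroscedasticity component has high power when residual variance grows
with the mean. A numerically perfect fit (zero residuals, as on noiseless
geometric families) skips the gate: there is nothing to diagnose.

`fit_fast_s()` is an S-estimator: it minimises an M-scale of the residuals
under the Tukey bisquare ρ at 50% breakdown (tuning constant c = 1.5476,
solved at construction from E[ρ] = 0.5 under the standard normal). The
search follows the fast-S recipe: 500 random p-point subsets, each improved
with 2 iteratively-reweighted least-squares steps, the best 5 candidates
iterated to convergence (tolerance 1e-7 on the coefficient step, at most
200 iterations), smallest final scale wins. The M-scale itself is solved by
the fixed-point iteration s² ← s²·mean(ρ(r/s))/b to relative tolerance
1e-10. Standard errors use the asymptotic covariance
s²·E[ψ²]/E[ψ′]²·(XᵀX)⁻¹ with a small-sample n/(n−p) correction; CIs use the
same t quantile as OLS. These counts (500/2/5) are standard practice for
fast-S; determinism is guaranteed by seeding the subset draws, and ties in
the final scale are broken by candidate order. The 50%-breakdown estimator
trades Gaussian efficiency (≈29%) for resistance: the tests verify it
tolerates 20% gross response contamination that visibly biases OLS.

## Orthogonal morphological terms

With a = log10(total SA), e = log10(exposed SA), c = log10(CT²), the three
term vectors are [1, −1.25, 0.25] (offset K), [1, 1, 1] (isometric I), and
[1.5, 0.75, −2.25] (shape S). The shape vector is the cross product of the
other two, with the sign chosen so that S increases with larger total and
exposed SA but thinner cortex; the three are mutually orthogonal, K and S
are exactly invariant under isometric scaling (areas ×λ², thickness ×λ),
and I shifts by 6·log10 λ. The terms are "unitless" only up to the unit of
measurement, so all inputs are standardised to mm/mm²/mm³ at read time;
group contrasts are invariant to that convention. For plots,
`zscore_to_controls()` standardises terms to the control distribution — the
statistics always operate on raw terms.

## Permutation inference

Group effects on scaling coefficients are the group × log-regressor
interaction; effects on the terms are group main effects. p-values come
from Freedman–Lane permutation: the reduced model (without the focal
column) is fitted, its residuals permuted about its fitted values, and the
focal t-statistic recomputed for each permuted response,
p = (1 + #{|t*| ≥ |t|})/(1 + n_perm) with ties counted. This scheme was
chosen because it is the standard for covariate-adjusted permutation
inference and reduces exactly to simple response permutation when there are
no nuisance covariates (the suite checks equality on a fixed seed, and
agreement with exhaustive enumeration at n = 6). Reported estimates and
CIs are parametric — permutation affects only p. Default n_perm = 5000.

Holm correction is applied over a *family of six* per group pair: the three
scaling interactions plus the three term effects. This family definition
reproduces exactly the published pattern of adjusted p-values used as a
worked example in the acceptance tests. Demographic analyses form one
family per predictor; a categorical predictor with more than two levels
(CHD lesion subtype) expands into Holm-corrected pairwise contrasts.

Comparisons of a control group against a clinical group whose scan window
is narrower are made on common PMA support: `filter_pma_overlap()` removes
reference-group records scanned outside the target group's [min, max] PMA
and reports the count. The operation is idempotent.

## Normative deviance and outcomes

`fit_normative()` fits a robust (fast-S, by default) model of each metric
on the control group — covariates PMA, PMA², sex, multiple birth, and
birth-weight z, plus the log regressor for the scaling metrics — and stores
the control residual mean and SD. Note the stored mean is not exactly zero
for a robust fit, which is why it is kept: `deviance_z()` computes
z = (observed − predicted − control mean)/control SD for any subject, so
controls score mean 0/SD 1 by construction, and a clinical subject's z
measures displacement from the typical population given their demographics.
The PMA centring constant of the control fit is stored and reused when
scoring other groups, otherwise the PMA² column would silently change
meaning. Where descriptions of the covariate set conflict (with or without
the birth-weight z-score), the fuller set is the default and the argument
accepts any other set.

Outcome models are `outcome ~ z × group + socioeconomic rank` (IMD rank is
used as the numeric covariate — the finer measure compared with quintiles —
and the parent-English-language flag is added for language outcomes).
The interaction p is Freedman–Lane; per-group simple slopes are reported
post hoc with parametric p (the permutation machinery targets the
interaction, and the simple slopes are descriptive). Six metrics per
outcome form one Holm family. `bootstrap_delta_r2()` reports the
incremental R² of z over the covariate-only model; the point estimate is
the original-sample ΔR² and the CI is a percentile interval over
case-resampling replicates (n_boot = 2000 by default, minimum 100) — the
bootstrap quantifies uncertainty rather than redefining the estimator.

## The synthetic generator

`generate_cohort()` produces cohorts with the structure the analysis
assumes, and its defaults *are* the study conditions: groups of 345
controls, 73 preterm, 107 CHD; folding exponents 1.26/1.41/1.18; term
shifts matching the reported group contrasts (offset −0.012, isometric
+0.035, shape −0.141 for preterm; −0.004/−0.047/−0.051 for CHD); scans
uniform on 37 to 44+6 weeks PMA (CHD restricted to 37.14–42.29, so the PMA
overlap filter has work to do); gestational age uniform within group ranges
(37–42 term, 23–32.86 preterm); sex Bernoulli(0.5), multiple birth
Bernoulli(0.05), birth-weight z standard normal — only ranges, not
distributions, are reported for such cohorts, so uniform/Bernoulli choices
are ours. Outcome scores are 100 + slope·(true shape deviance z) + IMD
effect + N(0, 15), with slope −4.78 points per z in the preterm group only,
observed in follow-up subsamples of 57 preterm and 65 CHD infants.

Mechanics worth knowing:

* Noise enters on the log10 scale (multiplicative on the natural scale),
  consistent with fitting log-log regressions. The folding noise SD
  defaults to 0.01 log10 units.
* The folding lines of all groups pivot about the mean log exposed SA
  (default 4.48 ≈ 300 cm²), not about zero; otherwise changing the exponent
  would drive the gyrification index below 1.
* Volume is *derived* from total SA by inverting the SA–volume relation
  (slope 0.873, noise SD 0.001 — small relative to size variation, so the
  regression-attenuation bias on the SA–volume exponent is an order of
  magnitude below its SE), making volume the common regressor of two
  estimable models rather than an independent draw.
* Thickness couples weakly to size (default +0.125 log10 CT per log10
  exposed SA), giving the CT–volume model signal. The implied CT–volume
  exponent is *not* calibrated to any published value — individual-metric
  coefficients on real data are not reproducible from synthetic data, and
  no test pretends otherwise.
* Group term shifts are applied along the orthogonal term directions
  (Δ·v/‖v‖²), so each shift moves exactly its own term when group
  exponents are equal. When exponents differ, a group's mean offset also
  absorbs (α − 1.25)·(mean size displacement); the generator reproduces the
  configured shifts exactly only in the equal-exponent case, which is what
  the recovery tests use.
* The "true" shape deviance driving outcomes is computed inside the
  generator exactly the way the normative module later estimates it
  (control covariate model, control-standardised residuals), so recovery of
  the outcome slope is a genuine end-to-end check.

What the generator does **not** emulate: regional or vertex-wise variation
(whole-brain scalars only), non-Gaussian morphometric noise, measurement
error correlated across metrics, missing-not-at-random follow-up, secular
or scanner effects, and any real correlation between IMD and brain
measures. Tests passing on synthetic cohorts therefore validate the
*machinery* — estimator consistency, calibration of permutation p-values,
family-wise error control, deviance bookkeeping — not the biological
conclusions one would draw from real data.

## Degenerate inputs and edge policies

Non-positive morphometrics are errors before any log transform. Constant
residuals make the assumption check meaningless and raise a degenerate-
input error (except the perfect-fit bypass in `fit_scaling()`). Rows
violating record invariants at read time are excluded and enumerated in a
validation report, never silently fixed; a missing required column is a
schema error naming the column. Permutation p-values are never zero (the +1
correction) and ties count as exceedances. Holm receives exact p-values;
rounding happens only at display.

## Problem sizes in the test suite

The suite favours a few deep, parameterised checks: coverage of the folding
CI over 200 replicate cohorts of n = 300; permutation-null uniformity over
400 replicates (199 permutations each); family-wise error over 200
replicate six-test families; power of the interaction test over 60
replicates at the study's group sizes (345/73). These sizes give binomial
Monte-Carlo error comfortably inside the asserted tolerances while keeping
the default run fast.

## Known limitations

* Exponents and terms are whole-brain; regional scaling may differ and is
  out of scope.
* The robust CI uses the asymptotic S-estimator covariance; at small n it
  can be optimistic compared with a bootstrap.
* Simple slopes in outcome models are parametric, not permutation-based.
* No real cohort data ship with the package, so coefficient reproduction on
  real data is represented by a (deliberately failing) placeholder test that
  activates when a user supplies the original cohort's derived table;
  synthetic parameter-recovery checks stand in for it.
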