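---
title: "Joint score tests for differential methylation and variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint score tests for differential methylation and variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointDV)
```

## The problem and the model

Case/control methylation studies usually ask whether the *mean* beta
value of a CpG site differs between groups.  But the *variability* of
methylation is disease-relevant in its own right, so a test of the joint
null

$$H_0:\ \mu_0 = \mu_1 \ \text{and}\ \sigma_0^2 = \sigma_1^2$$

is more appropriate than a mean-only test.  jointDV attacks this through
a logistic regression of disease status on the measurement and a
dispersion proxy,

$$\mathrm{logit}\,P(Y_i = 1 \mid x_i, z_i) = \beta_0 + \beta_1 x_i + \beta_2 z_i,$$

where $z_i$ is a within-group deviation of subject $i$'s value from its
own group's center.  The joint null is recast as
$H_0': \beta_1 = \beta_2 = 0$ and tested by the Rao score statistic at
the null fit ($\hat\beta_0 = \mathrm{logit}(\bar y)$, no coefficients
estimated):

$$T = \mathbf{U}^\top \widehat{\Sigma}^{-1} \mathbf{U}, \qquad
\mathbf{U} = \Bigl(\textstyle\sum_i x_i (y_i - \bar y),\
\sum_i z_i (y_i - \bar y)\Bigr)^\top,$$

$$\widehat{\Sigma} = n \bar y (1 - \bar y)
\begin{pmatrix} \hat\sigma_x^2 & \hat\sigma_{xz} \\
\hat\sigma_{xz} & \hat\sigma_z^2 \end{pmatrix},$$

with *divisor-n* pooled sample moments.  The divisor matters: with
divisor $n$ the quadratic form coincides exactly with the Rao score
statistic of the logistic model (the test suite verifies this against a
from-scratch score/information computation to $10^{-8}$).  Because
$x$ and $z$ enter the logistic likelihood as fixed regressors, the null
distribution of $T$ is $\chi^2_2$ regardless of the distribution of the
measurements — the source of the tests' robustness to non-normality.

Four choices of $z$ give the four variants:

| variant | $z_i$ | group center |
|---|---|---|
| AW      | squared deviation  | mean |
| iAW.Lev | absolute deviation | mean |
| iAW.BF  | absolute deviation | median |
| iAW.TM  | absolute deviation | 25% trimmed mean |

The absolute-deviation variants retain the measurement scale and damp
the influence of outliers; among them the median-centered iAW.BF is the
most robust across skewed, bimodal and contaminated data.

```{r}
x <- c(1, 2, 4, 8)
g <- c(0, 0, 1, 1)
joint_score_test(x, g, variant = "aw")
```

Two classical comparators are included: `joint_lrt()`, the normal-theory
$-2\log\Lambda$ for simultaneous mean/variance equality with
maximum-likelihood (divisor-$n$) variances and $\chi^2_2$ asymptotics,
and `ks_test2()`, the two-sample Kolmogorov–Smirnov test with the
asymptotic calibration.

## Parameters that matter

* `trim` (default 0.25): trimming proportion per tail for the iAW.TM
  center.  `k = floor(trim * n_g)` order statistics are removed from
  each tail of each group; ties are resolved by order-statistic
  position.  For even group sizes the median is the midpoint of the two
  central order statistics.
* Degenerate inputs: when $\widehat\Sigma$ is singular to working
  precision (determinant below $10^{-12}$ times the product of its
  diagonal — e.g. a constant site, or equally spaced values making the
  squared deviations constant) the test raises a classed
  degenerate-input condition rather than pseudo-inverting, because a
  pseudo-inverse would silently change the null distribution.
  `methyl_scan()` converts this into a flagged missing result.
* p-values are inherently two-sided (quadratic form); no one-sided
  option exists.  Missing values are rejected at input; imputation is
  out of scope.

## The simulation engine

`scenario_spec()` describes a two-group generating law: one of four
families (normal; Beta; chi-squared with optional location/scale; a
two-component normal mixture), per-group parameters, group sizes, an
outlier flag and a seed.  The scenario taxonomy follows the four-way
classification *eqM&eqV* (null), *diffM&eqV*, *eqM&diffV*,
*diffM&diffV*.

The outlier rule replaces the value of one uniformly chosen case by
$\max\{x_{1,\max},\ Q_3 + 3(Q_3 - Q_1)\}$ computed on the case group
before replacement.  Quartiles use `stats::quantile()` type 7 (the R
default linear-interpolation convention) — the rule's other ingredient,
the case maximum, makes case-group quartiles the coherent reading — and
the convention is isolated behind the `qtype` argument of
`inject_outlier()` so it can be swapped.

`estimate_type1()` runs 10,000 replicates (by default) of a null
scenario and reports, per test and level, the fraction of replicates
with $p < \alpha$ strictly.  All tests are applied to the *same*
replicate samples (a paired design, which removes between-test Monte
Carlo noise), and the tests consume no randomness, so adding a test
never perturbs the data stream.  Degenerate replicates count as
non-rejections and are tallied in the output — at 20+ subjects per group
with continuous data they essentially never occur.

Power is size-corrected: `corrected_cutoffs()` takes the null-run
statistics and returns the empirical upper-$\alpha$ critical value (the
$\lceil (1-\alpha) N \rceil$-th order statistic), and `estimate_power()`
counts statistics exceeding that cutoff, so that reported power is
comparable across tests whose asymptotic calibration is imperfect.
Re-applied to the generating null statistics, the corrected cutoff
reproduces the nominal level to within $1/N$ by construction.

Only the normal *null* scenario is treated as quantitative ground truth
for the published operating characteristics: the score tests and the
likelihood ratio test are invariant under affine transformations of the
data and KS under monotone ones, so the null rejection rates for the
normal family are parameter-free.  The alternative-scenario parameters
of the original study are not public; the shipped defaults (case SD
multiplied by 2 under *diffV*, case mean shifted by half an SD under
*diffM*) are illustrative and fully user-configurable.

Problem sizes in the shipped checks: the two quantitative null
comparisons use 10,000 replicates at $n_0 = n_1 = 100$; the qualitative
outlier-contrast check uses 2,000 replicates; KS conservativeness uses
5,000; the cutoff protocol is exercised at 1,000–2,000 replicates.

## The scanning pipeline

`filter_sites()` implements the probe filters: drop sites with any
missing value, drop probe ids with a `"ch"` prefix (non-CpG probes),
and — when a detection p-value matrix is supplied — drop sites with any
detection p-value greater than **or equal to** the threshold (the
boundary is inclusive).  `residualize()` replaces each site's values by
OLS residuals on an intercept plus the named covariates (age, cell-type
proportions, ...); the group label is deliberately excluded from the
design, and a rank-deficient design is an error naming the collinear
columns.  `methyl_scan()` applies one test per site, excludes degenerate
sites from the Benjamini–Hochberg input (this changes the number of
tests $m$, so the count is reported loudly), and records per-site
direction summaries: the case-minus-control difference of medians and of
mean absolute deviations.  The mean absolute deviation is taken about
the group *median* by default — the robust reading, consistent with the
median-centered test variant — with about-the-mean available via
`mad_center = "mean"`.

`discovery_validation()` implements the two-cohort design: a site is a
discovery if its FDR-adjusted p-value is below 0.05; it validates if its
*unadjusted* p-value in the second cohort is below 0.05; it is *truly*
validated if additionally the median-difference sign **and** the
MAD-difference sign agree between cohorts (the conjunction is the strict
reading of direction consistency; an either-sign mode is available but
off by default).  A direction difference of exactly zero counts as
inconsistent, and sites degenerate in either cohort never validate.
`split_cohort()` provides the seeded, group-stratified half-split used
for single-cohort discovery/validation designs.

## What the synthetic cohorts emulate — and what they do not

`simulate_methyl_cohorts()` generates paired cohorts over a shared site
panel: Gaussian values around per-site baselines in $[0.2, 0.8]$ with a
planted block of sites whose case SD is multiplied by `sd_ratio` in both
cohorts, optional per-site case outliers.  This emulates residualized
beta values with a reproducible differential-variability signal and is
the fixture generator for the end-to-end tests.  It does *not* emulate
several features of real arrays: per-site distributional heterogeneity
(skewness, bimodality varying across the panel), cohort-specific
technical artifacts, spatial/probe-type effects, or correlated sites.
Consequently, passing end-to-end tests demonstrate the pipeline's
bookkeeping and the tests' relative power under controlled conditions,
not performance on real cohorts.

One published contrast does not reproduce under this clean design, and
we report it rather than engineer around it: in the real-data analyses
the median-based variant showed a higher true-validation proportion than
the squared-deviation test.  Synthetically, the squared-deviation test's
response to an injected outlier is strictly *conservative* (its
statistic stays bounded as the outlying deviation grows), so it gains no
false discoveries; with planted variance shifts its discovery set is
either empty, or identical to the robust variant's (true-validation
proportions then tie exactly, since direction summaries do not depend on
the test), or — with heterogeneous effect sizes — slightly more enriched
in strong sites.  The corresponding end-to-end expectation is therefore
left failing by design, with the comparison computed honestly at a
well-powered configuration; the real-data ordering evidently reflects
distributional heterogeneity that this generator intentionally lacks.

## Numerical and design notes

* Rejection is $p < \alpha$ strictly; ties at the boundary have
  probability zero for continuous statistics and are not special-cased.
* The likelihood-ratio statistic is clipped at zero to absorb rounding
  when the two groups are identical.
* Whether the original jointLRT used divisor-$n$ or $n-1$ variances is
  not documented; pure MLE (divisor $n$) is used here, verified against
  a numerical profile-likelihood maximization.  No Bartlett-type
  correction is applied — the comparator is benchmarked as-is,
  inflation included.
* The trimmed mean with many tied values trims by order-statistic
  position; other tie conventions exist and would change iAW.TM slightly
  in heavily discretized data.
* Sample alignment between matrix and phenotype table is by id
  intersection, with dropped samples reported.

## Known limitations

Covariate adjustment is by upstream residualization only; there is no
covariate-adjusted score test.  The exact finite-sample distribution of
the likelihood ratio statistic is not implemented (asymptotics only, as
in the original benchmarks).  The pipeline reads whole matrices into
memory; EPIC-scale data (~850k sites) fit comfortably, but out-of-core
processing is not provided.
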