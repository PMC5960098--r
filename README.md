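# jointDV

Robust joint score tests of **equal means and equal variances** for
two-group (case/control) data, aimed at DNA methylation analysis where
differential *variability* of a CpG site carries disease signal beyond
differential mean methylation.

## The tests

For subject $i$ with measurement $x_i$ and disease label
$y_i \in \{0, 1\}$, the joint null $\mu_0 = \mu_1,\ \sigma_0^2 =
\sigma_1^2$ is recast as $\beta_1 = \beta_2 = 0$ in the logistic
regression

$$\mathrm{logit}\,P(Y_i = 1 \mid x_i, z_i) = \beta_0 + \beta_1 x_i + \beta_2 z_i,$$

where $z_i$ is a within-group dispersion proxy, and tested by the Rao
score statistic

$$T = \mathbf{U}^\top \widehat{\Sigma}^{-1} \mathbf{U}
  \ \sim\ \chi^2_2 \ \text{under } H_0,
\qquad
\mathbf{U} = \Bigl(\sum_i x_i (y_i - \bar y),\ \sum_i z_i (y_i - \bar y)\Bigr)^\top,$$

with $\widehat\Sigma = n \bar y (1-\bar y)\,
\widehat{\mathrm{Cov}}\bigl((x, z)\bigr)$ built from divisor-$n$ pooled
moments.  No coefficients are ever estimated.  Four choices of $z_i$
give four tests:

* **AW** — squared deviation from the group mean;
* **iAW.Lev** — absolute deviation from the group mean;
* **iAW.BF** — absolute deviation from the group *median* (the most
  robust across skewed, bimodal and outlier-contaminated data);
* **iAW.TM** — absolute deviation from the 25% trimmed group mean.

The normal-theory joint likelihood ratio test (`joint_lrt()`) and the
two-sample Kolmogorov–Smirnov test (`ks_test2()`) are included as
comparators, plus a Monte Carlo engine for empirical Type I error and
size-corrected power, and a per-CpG scanning pipeline (probe filtering,
covariate residualization, Benjamini–Hochberg discovery, two-cohort
validation with direction-consistency accounting).

## Worked example

A site measured on 24 controls and 24 cases whose case group is more
variable but not shifted in mean:

```r
library(jointDV)
set.seed(7)
x <- c(rnorm(24, 0.45, 0.05), rnorm(24, 0.45, 0.12))
g <- rep(0:1, each = 24)
joint_score_test(x, g, variant = "bf")
#> 	Joint score test of equal means and variances (iAW.BF)
#>
#> data:  x by g
#> T = 7.2434, df = 2, p-value = 0.02674
```

The statistic `T` is the chi-squared(2) quadratic form above; `p-value
= 0.027` rejects the joint null at 5% — here driven by the variance
component, which a mean-only test would miss.

Operating characteristics under a contaminated null (one injected case
outlier per replicate, $n_0 = n_1 = 100$):

```r
spec <- scenario_spec("normal", n0 = 100, n1 = 100, outlier = TRUE, seed = 42)
estimate_type1(spec, n_reps = 2000, alphas = c(0.05, 0.01))
#> Empirical rejection rates (x100), 2000 replicates
#>  alpha jointLRT   KS   AW iAW.Lev iAW.BF iAW.TM
#>   0.05     13.6 3.05 3.95     5.5   5.35    5.4
#>   0.01      4.1 0.45 0.35     0.8   0.80    0.8
```

The likelihood ratio test inflates (13.6% at a nominal 5%), the
squared-deviation AW test turns conservative (3.95%), while the three
robust variants hold their level — the package's reason for existing.

End-to-end discovery/validation on paired synthetic cohorts with ten
planted differentially variable sites:

```r
ch  <- simulate_methyl_cohorts(n_sites = 60, n_dv = 10, n0 = 40, n1 = 40,
                               sd_ratio = 3, seed = 1)
dsc <- methyl_scan(ch$discovery$beta,  ch$discovery$group,  "iAW.BF")
val <- methyl_scan(ch$validation$beta, ch$validation$group, "iAW.BF")
discovery_validation(dsc, val)
#>   nSig nValidation nTV pTV nFV pFV
#> 1   10          10   4  40   6  60
```

All ten planted sites are discovered (FDR < 0.05) and re-validated
(unadjusted p < 0.05 in the second cohort); `nTV` additionally requires
the median-difference and dispersion-difference signs to agree between
cohorts — with equal planted means the median direction is a coin flip,
so about half the validated sites count as direction-consistent.

A command-line front end over the same functions ships in
`inst/cli/jointDV.R` with subcommands `test`, `simulate`, `scan`,
`validate` and `split`.

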