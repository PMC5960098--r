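# Synthetic methylation cohorts with planted differentially variable
# sites: the package's fixture generator for end-to-end pipeline checks.

#' Simulate paired methylation cohorts with planted variance shifts
#'
#' Generates two independent case/control cohorts over a shared set of
#' sites.  A leading block of `n_dv` sites carries a true variance shift
#' (case standard deviation multiplied by `sd_ratio`) in *both* cohorts;
#' the remaining sites are null.  Values are Gaussian around a per-site
#' baseline level drawn uniformly in `[0.2, 0.8]` with residual standard
#' deviation `sd0`, emulating (approximately) beta values after covariate
#' residualization; with `outlier = TRUE` the case group of every site
#' receives one injected outlier by the rule of [inject_outlier()].
#'
#' @param n_sites total number of sites.
#' @param n_dv number of differentially variable sites (first rows).
#' @param n0,n1 controls and cases per cohort.
#' @param sd0 null within-group standard deviation.
#' @param sd_ratio case/control SD ratio at the planted sites.
#' @param outlier inject one case outlier per site and cohort.
#' @param seed integer seed (mandatory: fixtures must be reproducible).
#' @return list of two cohorts (`discovery`, `validation`), each a list
#'   with `beta` (matrix, row names `dv_*`/`null_*`) and `group`.
#' @export
simulate_methyl_cohorts <- function(n_sites = 200, n_dv = 20,
                                    n0 = 50, n1 = 50, sd0 = 0.05,
                                    sd_ratio = 3, outlier = FALSE,
                                    seed) {
  if (missing(seed)) stop_invalid("a seed is required")
  set.seed(seed)
  site_ids <- c(sprintf("dv_%03d", seq_len(n_dv)),
                sprintf("null_%03d", seq_len(n_sites - n_dv)))
  base <- stats::runif(n_sites, 0.2, 0.8)
  group <- rep(c(0L, 1L), c(n0, n1))
  make_cohort <- function(tag) {
    beta <- matrix(NA_real_, n_sites, n0 + n1,
                   dimnames = list(site_ids,
                                   paste0(tag, "_s", seq_len(n0 + n1))))
    for (i in seq_len(n_sites)) {
      sd1 <- if (i <= n_dv) sd0 * sd_ratio else sd0
      x <- c(rnorm(n0, base[i], sd0), rnorm(n1, base[i], sd1))
      if (outlier) x <- inject_outlier(x, group)
      beta[i, ] <- x
    }
    list(beta = beta, group = group)
  }
  list(discovery = make_cohort("d"), validation = make_cohort("v"))
}
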