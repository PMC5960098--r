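# Comparator tests: the normal-theory joint likelihood ratio test and the
# two-sample Kolmogorov-Smirnov test.

#' Joint likelihood ratio test of equal means and variances (normal theory)
#'
#' The -2 log likelihood ratio for simultaneous equality of the means and
#' variances of two normal populations, with maximum-likelihood
#' (divisor-n) variance estimates:
#' `statistic = n log s2 - n0 log s2_0 - n1 log s2_1`, where `s2_g` is the
#' within-group MLE variance and `s2` the pooled MLE variance about the
#' grand mean.  Calibrated against the asymptotic chi-squared distribution
#' with 2 degrees of freedom.
#'
#' @inheritParams joint_score_test
#' @return an object of class `c("joint_lrt", "htest")`.
#' @examples
#' joint_lrt(c(0, 2, 0, 4), c(0, 0, 1, 1))
#' @export
joint_lrt <- function(x, group) {
  dname <- paste(deparse1(substitute(x)), "by",
                 deparse1(substitute(group)))
  s <- check_two_group(x, group)
  x0 <- s$x[s$y == 0L]; x1 <- s$x[s$y == 1L]
  n0 <- s$n0; n1 <- s$n1; n <- n0 + n1
  v0 <- sum((x0 - mean(x0))^2) / n0
  v1 <- sum((x1 - mean(x1))^2) / n1
  if (v0 <= 0 || v1 <= 0)
    stop_degenerate("a group has zero variance; the log-likelihood ",
                    "ratio is undefined")
  v <- sum((s$x - mean(s$x))^2) / n
  stat <- n * log(v) - n0 * log(v0) - n1 * log(v1)
  stat <- max(stat, 0)  # guard against negative rounding at the null
  structure(list(
    statistic = c("-2 log LR" = stat),
    parameter = c(df = 2),
    p.value = pchisq(stat, df = 2, lower.tail = FALSE),
    method = "Joint likelihood ratio test of equal means and variances",
    data.name = dname
  ), class = c("joint_lrt", "htest"))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()] with the asymptotic Kolmogorov
#' calibration (`exact = FALSE`), i.e. the p-value is the asymptotic
#' Kolmogorov distribution evaluated at `sqrt(n0 n1 / (n0 + n1)) * D`,
#' `D = sup_t |F0(t) - F1(t)|`.  Ties (possible with rounded beta values)
#' are tolerated; the tie warning from `ks.test` is suppressed.
#'
#' @inheritParams joint_score_test
#' @return an object of class `"htest"` with statistic `D` in `[0, 1]`.
#' @export
ks_test2 <- function(x, group) {
  s <- check_two_group(x, group, min_per_group = 1L)
  res <- suppressWarnings(
    ks.test(s$x[s$y == 0L], s$x[s$y == 1L], exact = FALSE))
  res$data.name <- "control vs case values"
  res
}

#' Names of the six joint tests
#'
#' @return character vector `c("jointLRT", "KS", "AW", "iAW.Lev",
#'   "iAW.BF", "iAW.TM")`, the canonical benchmarking order.
#' @export
joint_tests <- function() {
  c("jointLRT", "KS", "AW", "iAW.Lev", "iAW.BF", "iAW.TM")
}

#' Run a joint test by name
#'
#' Dispatches to [joint_lrt()], [ks_test2()] or [joint_score_test()].
#' Accepts the canonical names from [joint_tests()] as well as the short
#' lower-case codes `"jointlrt"`, `"ks"`, `"aw"`, `"lev"`, `"bf"`, `"tm"`.
#'
#' @inheritParams joint_score_test
#' @param test test name (case-insensitive).
#' @return the `htest`-classed result of the selected test.
#' @export
run_joint_test <- function(x, group, test, trim = 0.25) {
  key <- sub("^iaw\\.", "", tolower(test))
  switch(key,
         jointlrt = joint_lrt(x, group),
         ks       = ks_test2(x, group),
         aw       = joint_score_test(x, group, "aw"),
         lev      = joint_score_test(x, group, "lev"),
         bf       = joint_score_test(x, group, "bf"),
         tm       = joint_score_test(x, group, "tm", trim = trim),
         stop_invalid("unknown test '", test, "'; see joint_tests()"))
}
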