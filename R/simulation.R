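# Monte Carlo engine: scenario specification, data generation under four
# parametric families, outlier injection, empirical Type I error and
# size-corrected power.

FAMILIES <- c("normal", "beta", "chisq", "normal_mixture")
SCENARIO_LABELS <- c("eqM&eqV", "diffM&eqV", "eqM&diffV", "diffM&diffV")

default_params <- function(family) {
  switch(family,
         normal         = list(mean = 0, sd = 1),
         beta           = list(shape1 = 2, shape2 = 5),
         chisq          = list(df = 3, location = 0, scale = 1),
         normal_mixture = list(mean1 = 0, mean2 = 3, sd1 = 1, sd2 = 1,
                               weight = 0.5))
}

check_params <- function(family, p, who) {
  need <- names(default_params(family))
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop_invalid(who, " parameters for family '", family,
                 "' missing: ", paste(miss, collapse = ", "))
  pos <- switch(family,
                normal = "sd", beta = c("shape1", "shape2"),
                chisq = c("df", "scale"),
                normal_mixture = c("sd1", "sd2"))
  for (nm in pos)
    if (p[[nm]] <= 0) stop_invalid(who, " parameter '", nm, "' must be > 0")
  if (family == "normal_mixture" &&
      (p$weight <= 0 || p$weight >= 1))
    stop_invalid(who, " mixing weight must lie strictly in (0, 1)")
  p[need]
}

#' Specify a two-group simulation scenario
#'
#' A scenario bundles the data-generating family, the per-group parameter
#' sets, the group sizes, the outlier flag, a scenario label from the
#' taxonomy (`eqM&eqV`, `diffM&eqV`, `eqM&diffV`, `diffM&diffV`) and an
#' optional RNG seed.  Under `eqM&eqV` the case parameters must equal the
#' control parameters.
#'
#' Families and their parameters: `normal` (`mean`, `sd`); `beta`
#' (`shape1`, `shape2`); `chisq` (`df`, plus optional `location`, `scale`
#' applied as `location + scale * draw`); `normal_mixture` (`mean1`,
#' `mean2`, `sd1`, `sd2`, `weight` = probability of component 1).
#' Omitted parameters take the documented defaults; `case` defaults to
#' `control`.
#'
#' @param family one of `"normal"`, `"beta"`, `"chisq"`,
#'   `"normal_mixture"`.
#' @param control,case named lists of family parameters.
#' @param n0,n1 control and case group sizes (each at least 2).
#' @param outlier if `TRUE`, each drawn sample has one case value replaced
#'   by the outlier-injection rule of [inject_outlier()].
#' @param label scenario label from the taxonomy above.
#' @param seed optional integer seed; when present, every run of the
#'   scenario is bit-reproducible.
#' @return an object of class `"scenario_spec"`.
#' @examples
#' scenario_spec("normal", n0 = 100, n1 = 100, seed = 1)
#' @export
scenario_spec <- function(family = FAMILIES, control = list(),
                          case = NULL, n0 = 100, n1 = 100,
                          outlier = FALSE, label = SCENARIO_LABELS,
                          seed = NULL) {
  family <- match.arg(family)
  label <- match.arg(label)
  control <- check_params(family,
                          utils::modifyList(default_params(family), control),
                          "control")
  case <- if (is.null(case)) control else
    check_params(family, utils::modifyList(control, case), "case")
  if (label == "eqM&eqV" && !identical(control, case))
    stop_invalid("under 'eqM&eqV' the case parameters must equal the ",
                 "control parameters")
  if (n0 < 2 || n1 < 2) stop_invalid("n0 and n1 must both be at least 2")
  structure(list(family = family, control = control, case = case,
                 n0 = as.integer(n0), n1 = as.integer(n1),
                 outlier = isTRUE(outlier), label = label, seed = seed),
            class = "scenario_spec")
}

draw_family <- function(family, p, n) {
  switch(family,
         normal = rnorm(n, p$mean, p$sd),
         beta   = rbeta(n, p$shape1, p$shape2),
         chisq  = p$location + p$scale * rchisq(n, p$df),
         normal_mixture = {
           comp1 <- rbinom(n, 1L, p$weight) == 1L
           ifelse(comp1, rnorm(n, p$mean1, p$sd1),
                  rnorm(n, p$mean2, p$sd2))
         })
}

# one sample from a spec using the current RNG state (no seed reset)
draw_once <- function(spec) {
  x <- c(draw_family(spec$family, spec$control, spec$n0),
         draw_family(spec$family, spec$case, spec$n1))
  g <- rep(c(0L, 1L), c(spec$n0, spec$n1))
  if (spec$outlier) x <- inject_outlier(x, g)
  data.frame(value = x, group = g)
}

#' Draw one two-group sample from a scenario
#'
#' Controls are drawn from the control family, cases from the case family;
#' when the scenario carries a seed the draw is reproducible.  The outlier
#' rule is applied when `spec$outlier` is `TRUE`.
#'
#' @param spec a [scenario_spec()].
#' @return a data frame with columns `value` and `group` (0/1).
#' @export
draw_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  draw_once(spec)
}

#' Inject a single outlier into the case group
#'
#' Replaces the value of one uniformly chosen case subject by
#' `max(x1max, Q3 + 3 * (Q3 - Q1))`, where `x1max` is the maximum case
#' value and `Q1`, `Q3` are the first and third quartiles of the case
#' values before replacement.  Quartiles are computed on the case group
#' only, by [stats::quantile()] with the given `type` (default 7, the R
#' default linear-interpolation convention).  Controls are untouched.
#'
#' @inheritParams joint_score_test
#' @param qtype quantile type passed to [stats::quantile()].
#' @return `x` with one case value replaced.
#' @examples
#' inject_outlier(c(0, 0, 1, 2, 3, 4, 5), c(0, 0, 1, 1, 1, 1, 1))
#' @export
inject_outlier <- function(x, group, qtype = 7) {
  s <- check_two_group(x, group, min_per_group = 1L)
  if (s$n1 < 2) stop_invalid("outlier injection needs at least 2 cases")
  idx <- which(s$y == 1L)
  cases <- s$x[idx]
  q <- quantile(cases, c(0.25, 0.75), names = FALSE, type = qtype)
  repl <- max(max(cases), q[2] + 3 * (q[2] - q[1]))
  pick <- idx[sample.int(length(idx), 1L)]
  x[pick] <- repl
  x
}

# workhorse: simulate n_reps samples and evaluate each requested test on
# every sample (paired design); returns statistic and p matrices with NA
# where the test raised a degenerate-input condition
simulate_tests <- function(spec, tests, n_reps, trim = 0.25) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (n_reps < 1) stop_invalid("n_reps must be at least 1")
  bad <- setdiff(tests, joint_tests())
  if (length(bad))
    stop_invalid("unknown test(s): ", paste(bad, collapse = ", "))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  stat <- matrix(NA_real_, n_reps, length(tests),
                 dimnames = list(NULL, tests))
  pval <- stat
  for (r in seq_len(n_reps)) {
    d <- draw_once(spec)
    for (tn in tests) {
      res <- tryCatch(run_joint_test(d$value, d$group, tn, trim = trim),
                      jointDV_degenerate = function(e) NULL)
      if (!is.null(res)) {
        stat[r, tn] <- unname(res$statistic)
        pval[r, tn] <- res$p.value
      }
    }
  }
  list(stat = stat, p = pval, degenerate = colSums(is.na(stat)))
}

rate_table <- function(reject, n_reps, degenerate, alphas, tests) {
  out <- expand.grid(test = tests, alpha = alphas,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rate <- mapply(function(tn, a) reject[[paste(tn, a)]], out$test,
                     out$alpha)
  out$n_reps <- n_reps
  out$mc_se <- sqrt(out$rate * (1 - out$rate) / n_reps)
  out$n_degenerate <- degenerate[out$test]
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Empirical Type I error rates under a null scenario
#'
#' Simulates `n_reps` samples from a null (`eqM&eqV`) scenario and, for
#' each test and nominal level, reports the fraction of replicates with
#' p-value strictly below the level.  Replicates on which a test raises a
#' degenerate-input condition (singular score covariance, zero-variance
#' group) are counted in the denominator as non-rejections and their count
#' is reported in the `n_degenerate` column.
#'
#' All tests are evaluated on the same simulated samples (a paired
#' design), so adding or removing tests does not change the data stream.
#'
#' @param spec a null [scenario_spec()] (`label = "eqM&eqV"`).
#' @param tests character vector of test names (see [joint_tests()]).
#' @param n_reps number of Monte Carlo replicates.
#' @param alphas nominal significance levels.
#' @param trim trimming proportion for iAW.TM.
#' @return a `rate_table` data frame with columns `test`, `alpha`, `rate`,
#'   `n_reps`, `mc_se`, `n_degenerate`, carrying the simulated statistics
#'   as attribute `"statistics"` (a replicates x tests matrix) for use
#'   with [corrected_cutoffs()].
#' @export
estimate_type1 <- function(spec, tests = joint_tests(), n_reps = 10000,
                           alphas = c(0.05, 0.01, 0.005), trim = 0.25) {
  if (spec$label != "eqM&eqV")
    stop_invalid("Type I error estimation requires a null scenario ",
                 "(label 'eqM&eqV'); got '", spec$label, "'")
  sim <- simulate_tests(spec, tests, n_reps, trim)
  reject <- list()
  for (tn in tests) for (a in alphas) {
    p <- sim$p[, tn]
    reject[[paste(tn, a)]] <- sum(p < a, na.rm = TRUE) / n_reps
  }
  out <- rate_table(reject, n_reps, sim$degenerate, alphas, tests)
  attr(out, "statistics") <- sim$stat
  out
}

#' Simulate null statistics for cutoff correction
#'
#' Runs the null scenario and returns the raw statistic matrix
#' (replicates x tests), the input to [corrected_cutoffs()].
#'
#' @inheritParams estimate_type1
#' @return numeric matrix with one column per test; `NA` marks degenerate
#'   replicates.
#' @export
null_statistics <- function(spec, tests = joint_tests(), n_reps = 10000,
                            trim = 0.25) {
  if (spec$label != "eqM&eqV")
    stop_invalid("null statistics require a null scenario (label ",
                 "'eqM&eqV'); got '", spec$label, "'")
  simulate_tests(spec, tests, n_reps, trim)$stat
}

#' Size-corrected critical values from null statistics
#'
#' For each test and nominal level alpha, the corrected cutoff is the
#' `ceiling((1 - alpha) * N)`-th order statistic of the N simulated null
#' statistics: the empirical upper-alpha critical value.  By construction,
#' re-applying the cutoff to the generating null statistics rejects at a
#' rate between `alpha - 1/N` and `alpha`.
#'
#' @param stats matrix of null statistics (replicates x tests, named
#'   columns) as from [null_statistics()], or a named list of numeric
#'   vectors.  `NA` entries (degenerate replicates) are dropped.
#' @param alphas nominal levels.
#' @return a `cutoff_table` data frame with columns `test`, `alpha`,
#'   `cutoff`.
#' @export
corrected_cutoffs <- function(stats, alphas = c(0.05, 0.01, 0.005)) {
  if (is.matrix(stats)) {
    cn <- colnames(stats)
    stats <- lapply(cn, function(j) stats[, j])
    names(stats) <- cn
  }
  out <- expand.grid(test = names(stats), alpha = alphas,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$cutoff <- mapply(function(tn, a) {
    v <- stats[[tn]]
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      stop_invalid("no non-degenerate null statistics for test '", tn, "'")
    sort(v)[ceiling((1 - a) * length(v))]
  }, out$test, out$alpha)
  class(out) <- c("cutoff_table", "data.frame")
  out
}

#' Size-corrected power under an alternative scenario
#'
#' Simulates `n_reps` samples from a non-null scenario and reports, per
#' test and level, the fraction of replicates whose statistic strictly
#' exceeds the corrected cutoff obtained from the matching null run.
#' Degenerate replicates count as non-rejections.
#'
#' @param spec an alternative [scenario_spec()] (label `diffM&eqV`,
#'   `eqM&diffV` or `diffM&diffV`).
#' @param cutoffs a `cutoff_table` from [corrected_cutoffs()].
#' @inheritParams estimate_type1
#' @return a `rate_table` data frame.
#' @export
estimate_power <- function(spec, tests = joint_tests(), cutoffs,
                           n_reps = 5000, trim = 0.25) {
  if (spec$label == "eqM&eqV")
    stop_invalid("power estimation requires a non-null scenario label")
  sim <- simulate_tests(spec, tests, n_reps, trim)
  alphas <- sort(unique(cutoffs$alpha))
  reject <- list()
  for (tn in tests) for (a in alphas) {
    cut <- cutoffs$cutoff[cutoffs$test == tn & cutoffs$alpha == a]
    if (length(cut) != 1L)
      stop_invalid("no corrected cutoff for test '", tn,
                   "' at alpha = ", a)
    reject[[paste(tn, a)]] <-
      sum(sim$stat[, tn] > cut, na.rm = TRUE) / n_reps
  }
  rate_table(reject, n_reps, sim$degenerate, alphas, tests)
}

#' @export
print.rate_table <- function(x, digits = 3, ...) {
  cat("Empirical rejection rates (x100), ", x$n_reps[1L],
      " replicates\n", sep = "")
  w <- stats::reshape(as.data.frame(x)[, c("test", "alpha", "rate")],
                      idvar = "alpha", timevar = "test",
                      direction = "wide")
  names(w) <- sub("^rate\\.", "", names(w))
  w[-1L] <- lapply(w[-1L], function(v) round(100 * v, digits - 1L))
  print(w, row.names = FALSE)
  invisible(x)
}
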