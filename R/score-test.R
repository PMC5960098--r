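# Joint score tests of equal means and equal variances.
#
# All four variants share one construction: a logistic regression of the
# binary disease label y on the measurement x and a within-group dispersion
# proxy z, tested by the Rao score statistic at the null fit
# (beta1 = beta2 = 0, beta0 = logit(ybar)).  The variants differ only in z.

DEVIATION_METHODS <- c("squared_from_mean", "abs_from_mean",
                       "abs_from_median", "abs_from_trimmed_mean")

VARIANT_METHOD <- c(aw  = "squared_from_mean",
                    lev = "abs_from_mean",
                    bf  = "abs_from_median",
                    tm  = "abs_from_trimmed_mean")

VARIANT_LABEL <- c(aw = "AW", lev = "iAW.Lev", bf = "iAW.BF", tm = "iAW.TM")

# canonicalize (x, group) into values + 0/1 labels, enforcing the
# two-group invariants: equal lengths, finite values, both groups >= 2
check_two_group <- function(x, group, min_per_group = 2L) {
  if (length(x) != length(group))
    stop_invalid("'x' and 'group' must have the same length")
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop_invalid("'x' must be numeric with all values finite (no NA)")
  if (is.factor(group)) group <- as.integer(group) - 1L
  if (is.logical(group)) group <- as.integer(group)
  if (anyNA(group) || !all(group %in% c(0, 1)))
    stop_invalid("'group' must be binary: 0/FALSE = control, 1/TRUE = case")
  y <- as.integer(group)
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (n0 < min_per_group || n1 < min_per_group)
    stop_invalid("each group needs at least ", min_per_group,
                 " subjects (got n0 = ", n0, ", n1 = ", n1, ")")
  list(x = as.numeric(x), y = y, n0 = n0, n1 = n1)
}

#' Trimmed mean with order-statistic trimming
#'
#' Mean of the values remaining after removing the `k = floor(trim * n)`
#' smallest and `k` largest order statistics.  With `trim = 0.25` this is
#' the 25% trimmed mean used by the iAW.TM test: the sample mean after
#' trimming the 25% lowest and 25% highest values.  Ties are resolved by
#' order-statistic position.
#'
#' @param x numeric vector, non-empty, no missing values.
#' @param trim trimming proportion per tail, in `[0, 0.5)`.
#' @return the trimmed mean (a single number).
#' @examples
#' trimmed_mean(c(1, 2, 3, 4, 100), 0.25)  # 3: mean of 2, 3, 4
#' @export
trimmed_mean <- function(x, trim = 0.25) {
  if (length(x) == 0L) stop_invalid("'x' must be non-empty")
  if (anyNA(x)) stop_invalid("'x' must not contain missing values")
  if (!is.numeric(trim) || length(trim) != 1L || trim < 0 || trim >= 0.5)
    stop_invalid("'trim' must be a single value in [0, 0.5)")
  k <- floor(trim * length(x))
  if (2 * k >= length(x))
    stop_invalid("trimming removes all observations (2k >= n)")
  if (k == 0L) return(mean(x))
  s <- sort(x)
  mean(s[(k + 1L):(length(x) - k)])
}

# group center for a deviation method
group_center <- function(v, method, trim) {
  switch(method,
         squared_from_mean     = mean(v),
         abs_from_mean         = mean(v),
         abs_from_median       = median(v),
         abs_from_trimmed_mean = trimmed_mean(v, trim))
}

#' Within-group deviation vector
#'
#' Computes the per-subject dispersion proxy z used by the joint score
#' tests.  Each subject's deviation is taken from a center computed within
#' that subject's own group: the group mean (squared or absolute
#' deviation), the group median, or the 25% trimmed group mean.
#'
#' @param x numeric measurements, one per subject.
#' @param group binary labels (0 = control, 1 = case), same length as `x`.
#' @param method one of `"squared_from_mean"` (AW), `"abs_from_mean"`
#'   (iAW.Lev), `"abs_from_median"` (iAW.BF), `"abs_from_trimmed_mean"`
#'   (iAW.TM).
#' @param trim trimming proportion for the trimmed-mean center.
#' @return a list with components `z` (nonnegative deviations in subject
#'   order), `method`, and `centers` (control center, case center).
#' @examples
#' within_group_deviation(c(1, 2, 4, 8), c(0, 0, 1, 1), "abs_from_median")
#' @export
within_group_deviation <- function(x, group,
                                   method = DEVIATION_METHODS,
                                   trim = 0.25) {
  method <- match.arg(method)
  s <- check_two_group(x, group)
  c0 <- group_center(s$x[s$y == 0L], method, trim)
  c1 <- group_center(s$x[s$y == 1L], method, trim)
  ctr <- ifelse(s$y == 1L, c1, c0)
  z <- if (method == "squared_from_mean") (s$x - ctr)^2 else abs(s$x - ctr)
  list(z = z, method = method, centers = c(control = c0, case = c1))
}

#' Score vector of the joint logistic score test
#'
#' The two score components at the null fit of the logistic regression of
#' labels on (x, z): `U1 = sum(x_i (y_i - ybar))` and
#' `U2 = sum(z_i (y_i - ybar))`, with `ybar = n1 / n`.
#'
#' @inheritParams within_group_deviation
#' @param z deviation vector as produced by [within_group_deviation()]
#'   (either the list or the bare numeric vector).
#' @return numeric 2-vector `(U1, U2)`.
#' @export
score_vector <- function(x, group, z) {
  s <- check_two_group(x, group)
  if (is.list(z)) z <- z$z
  yc <- s$y - s$n1 / (s$n0 + s$n1)
  c(U1 = sum(s$x * yc), U2 = sum(z * yc))
}

#' Null covariance estimate of the score vector
#'
#' `Sigma = n ybar (1 - ybar)` times the 2x2 matrix of overall sample
#' variances/covariance of x and z, each with divisor n (not n - 1).  The
#' moments are pooled over both groups; the divisor matters for exact
#' agreement with the Rao score statistic.
#'
#' @inheritParams score_vector
#' @return symmetric 2x2 matrix.
#' @export
score_covariance <- function(x, group, z) {
  s <- check_two_group(x, group)
  if (is.list(z)) z <- z$z
  n <- s$n0 + s$n1
  ybar <- s$n1 / n
  xc <- s$x - mean(s$x)
  zc <- z - mean(z)
  m <- matrix(c(sum(xc * xc), sum(xc * zc),
                sum(xc * zc), sum(zc * zc)) / n, 2L, 2L)
  n * ybar * (1 - ybar) * m
}

# quadratic form U' Sigma^{-1} U with an explicit 2x2 inverse; singularity
# detected on the determinant relative to the diagonal scale (tol 1e-12)
quad_form_2x2 <- function(U, Sigma, tol = 1e-12) {
  s11 <- Sigma[1L, 1L]; s22 <- Sigma[2L, 2L]; s12 <- Sigma[1L, 2L]
  det <- s11 * s22 - s12 * s12
  scale <- s11 * s22
  if (!(scale > 0) || !(det > tol * scale))
    stop_degenerate("score covariance matrix is singular to working ",
                    "precision (sigma_x^2 = ", signif(s11, 6),
                    ", sigma_z^2 = ", signif(s22, 6),
                    ", det = ", signif(det, 6), ")")
  (s22 * U[1L]^2 - 2 * s12 * U[1L] * U[2L] + s11 * U[2L]^2) / det
}

#' Joint score test of equal means and equal variances
#'
#' Tests the two-group null hypothesis of equal means and equal variances
#' by the Rao score test of the logistic regression
#' `logit P(Y = 1 | x, z) = b0 + b1 x + b2 z`, where z is a within-group
#' dispersion proxy.  The statistic `T = U' Sigma^-1 U` is referred to the
#' chi-squared distribution with 2 degrees of freedom.  No regression
#' coefficients are estimated; the test is evaluated entirely at the null.
#'
#' Variants: `"aw"` uses the within-group squared deviation from the group
#' mean; `"lev"`, `"bf"` and `"tm"` use the absolute deviation from the
#' group mean, group median and 25% trimmed group mean respectively, which
#' makes them robust to outlying and skewed methylation values.
#'
#' @param x numeric measurements (e.g. methylation beta values or
#'   residuals), one per subject.
#' @param group binary labels (0 = control, 1 = case), same length as `x`;
#'   a two-level factor or logical is accepted.
#' @param variant `"aw"`, `"lev"`, `"bf"` or `"tm"`.
#' @param trim trimming proportion per tail for `variant = "tm"`;
#'   default 0.25.
#' @return an object of class `c("joint_score_test", "htest")` with
#'   components `statistic`, `parameter` (df = 2), `p.value`, `score`
#'   (the 2-vector U), `sigma` (the estimated covariance of U), `variant`
#'   and `centers`.
#' @examples
#' x <- c(1, 2, 4, 8)
#' g <- c(0, 0, 1, 1)
#' joint_score_test(x, g, "aw")   # T = 4, p = exp(-2)
#' @export
joint_score_test <- function(x, group, variant = c("aw", "lev", "bf", "tm"),
                             trim = 0.25) {
  variant <- match.arg(variant)
  dname <- paste(deparse1(substitute(x)), "by",
                 deparse1(substitute(group)))
  s <- check_two_group(x, group)
  dev <- within_group_deviation(s$x, s$y, VARIANT_METHOD[[variant]], trim)
  U <- score_vector(s$x, s$y, dev$z)
  Sigma <- score_covariance(s$x, s$y, dev$z)
  stat <- quad_form_2x2(unname(U), Sigma)
  structure(list(
    statistic = c(T = stat),
    parameter = c(df = 2),
    p.value = pchisq(stat, df = 2, lower.tail = FALSE),
    method = paste0("Joint score test of equal means and variances (",
                    VARIANT_LABEL[[variant]], ")"),
    data.name = dname,
    score = U,
    sigma = Sigma,
    variant = variant,
    centers = dev$centers
  ), class = c("joint_score_test", "htest"))
}
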