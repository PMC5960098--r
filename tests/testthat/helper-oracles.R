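# Independent oracles used across the suite.  Each recomputes a quantity
# from first principles, sharing no code path with the package internals.

# Rao score statistic of the logistic regression of y on (x, z) at the
# null fit (b1 = b2 = 0, b0 = logit(ybar)): U' I^{-1} U on the full
# design, where the intercept score is 0 at the null fit so the quadratic
# form equals the efficient score statistic for (b1, b2).
rao_score_oracle <- function(x, y, z) {
  X <- cbind(1, x, z)
  ybar <- mean(y)
  U <- drop(crossprod(X, y - ybar))
  I <- ybar * (1 - ybar) * crossprod(X)
  drop(t(U) %*% solve(I) %*% U)
}

# hand-coded quadratic form for a joint score test, written directly from
# the defining sums (no shared helpers)
hand_joint_score <- function(x, y, z) {
  n <- length(x)
  ybar <- sum(y) / n
  U <- c(sum(x * (y - ybar)), sum(z * (y - ybar)))
  sxx <- sum((x - mean(x))^2) / n
  szz <- sum((z - mean(z))^2) / n
  sxz <- sum((x - mean(x)) * (z - mean(z))) / n
  Sigma <- n * ybar * (1 - ybar) * matrix(c(sxx, sxz, sxz, szz), 2, 2)
  drop(t(U) %*% solve(Sigma) %*% U)
}

# -2 log likelihood ratio for equal normal means and variances, obtained
# by numerically maximizing the two-normal likelihood under the null
# (common mean, common variance) and the alternative (free per-group
# parameters), started from the moment estimates
lrt_oracle <- function(x0, x1) {
  nll_alt <- function(th)
    -sum(dnorm(x0, th[1], exp(th[2]), log = TRUE)) -
      sum(dnorm(x1, th[3], exp(th[4]), log = TRUE))
  nll_null <- function(th)
    -sum(dnorm(c(x0, x1), th[1], exp(th[2]), log = TRUE))
  start_alt <- c(mean(x0), log(sqrt(mean((x0 - mean(x0))^2))),
                 mean(x1), log(sqrt(mean((x1 - mean(x1))^2))))
  pooled <- c(x0, x1)
  start_null <- c(mean(pooled), log(sqrt(mean((pooled - mean(pooled))^2))))
  oa <- optim(start_alt, nll_alt, method = "BFGS",
              control = list(reltol = 1e-14, maxit = 1000))
  on <- optim(start_null, nll_null, method = "BFGS",
              control = list(reltol = 1e-14, maxit = 1000))
  2 * (on$value - oa$value)
}

# brute-force Benjamini-Hochberg step-up: sort, scale by m/rank, enforce
# monotonicity from the largest rank down, cap at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# random two-group sample from a mix of distributions, for property loops
random_two_group <- function(n0, n1) {
  fam <- sample(c("normal", "beta", "chisq", "mixture"), 1)
  gen <- function(n) switch(fam,
    normal = rnorm(n),
    beta = rbeta(n, 2, 5),
    chisq = rchisq(n, 3),
    mixture = ifelse(runif(n) < 0.5, rnorm(n, 0, 1), rnorm(n, 3, 2)))
  list(x = c(gen(n0), gen(n1)),
       y = rep(c(0L, 1L), c(n0, n1)))
}
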