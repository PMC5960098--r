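# Monte Carlo engine: scenario validity, reproducibility, outlier rule,
# cutoff correction and power protocol.

test_that("scenario_spec validates the taxonomy and parameters", {
  expect_error(scenario_spec("normal", case = list(mean = 1),
                             label = "eqM&eqV"),
               class = "jointDV_invalid_input")
  expect_error(scenario_spec("normal", control = list(sd = 0)),
               class = "jointDV_invalid_input")
  expect_error(scenario_spec("normal_mixture",
                             control = list(weight = 1)),
               class = "jointDV_invalid_input")
  expect_error(scenario_spec("normal", n0 = 1),
               class = "jointDV_invalid_input")
  sp <- scenario_spec("normal", case = list(mean = 0.5),
                      label = "diffM&eqV")
  expect_equal(sp$case$mean, 0.5)
  expect_equal(sp$case$sd, 1)     # inherits the control sd
})

test_that("draws are reproducible and respect family supports", {
  sp <- scenario_spec("beta", n0 = 50, n1 = 50, seed = 11)
  d1 <- draw_scenario(sp); d2 <- draw_scenario(sp)
  expect_identical(d1, d2)
  expect_true(all(d1$value > 0 & d1$value < 1))
  expect_equal(table(d1$group)[["0"]], 50)
  chi <- draw_scenario(scenario_spec("chisq", n0 = 50, n1 = 50, seed = 12))
  expect_true(all(chi$value >= 0))
  mix <- draw_scenario(scenario_spec("normal_mixture", n0 = 200, n1 = 200,
                                     seed = 13))
  expect_equal(length(mix$value), 400)
})

test_that("outlier rule replaces one case by max(case max, Q3 + 3 IQR)", {
  set.seed(21)
  x <- c(9, 9, 1, 2, 3, 4, 5); g <- c(0, 0, 1, 1, 1, 1, 1)
  out <- inject_outlier(x, g)
  changed <- which(out != x)
  expect_length(changed, 1)
  expect_true(changed >= 3)                 # controls untouched
  expect_equal(out[changed], 10)            # Q1 = 2, Q3 = 4 -> 4 + 6
  # constant cases: replacement equals the constant, sample unchanged
  xc <- c(0, 1, 7, 7, 7, 7)
  expect_equal(inject_outlier(xc, c(0, 0, 1, 1, 1, 1)), xc)
  # replacement never below the case maximum
  for (i in 1:10) {
    xx <- rnorm(30); gg <- rep(0:1, each = 15)
    expect_true(max(inject_outlier(xx, gg)[gg == 1]) >= max(xx[gg == 1]))
  }
})

test_that("Type I error estimation is reproducible and level-monotone", {
  sp <- scenario_spec("normal", n0 = 30, n1 = 30, seed = 31)
  r1 <- estimate_type1(sp, tests = c("AW", "iAW.BF"), n_reps = 300,
                       alphas = c(0.05, 0.2, 1))
  r2 <- estimate_type1(sp, tests = c("AW", "iAW.BF"), n_reps = 300,
                       alphas = c(0.05, 0.2, 1))
  expect_identical(r1$rate, r2$rate)
  expect_true(all(r1$rate[r1$alpha == 1] == 1))   # everything rejected
  for (tn in c("AW", "iAW.BF")) {
    rr <- r1$rate[r1$test == tn][order(r1$alpha[r1$test == tn])]
    expect_true(all(diff(rr) >= 0))
  }
  expect_error(estimate_type1(scenario_spec("normal",
                                            case = list(mean = 1),
                                            label = "diffM&eqV")),
               class = "jointDV_invalid_input")
})

test_that("corrected cutoffs are the empirical upper-alpha order statistics", {
  stats <- list(AW = as.numeric(1:100))
  ct <- corrected_cutoffs(stats, alphas = c(0.05, 0.01))
  expect_equal(ct$cutoff[ct$alpha == 0.05], 95)
  expect_equal(ct$cutoff[ct$alpha == 0.01], 99)
  tiny <- corrected_cutoffs(stats, alphas = 1e-9)
  expect_equal(tiny$cutoff, 100)                 # alpha -> 0 gives the max
  # cutoffs decrease as alpha increases
  expect_true(ct$cutoff[ct$alpha == 0.05] < ct$cutoff[ct$alpha == 0.01])
  # re-applied to the generating null statistics: rate in [alpha - 1/N, alpha]
  set.seed(41)
  v <- rchisq(1000, 2)
  for (a in c(0.05, 0.01)) {
    cut <- corrected_cutoffs(list(t = v), a)$cutoff
    rate <- mean(v > cut)
    expect_lte(rate, a)
    expect_gte(rate, a - 1 / length(v))
  }
  expect_error(corrected_cutoffs(list(AW = numeric(0)), 0.05),
               class = "jointDV_invalid_input")
})

test_that("size-corrected power saturates under a strong mean shift", {
  tests <- c("AW", "iAW.BF")
  null_sp <- scenario_spec("normal", n0 = 100, n1 = 100, seed = 51)
  cuts <- corrected_cutoffs(null_statistics(null_sp, tests,
                                            n_reps = 1000),
                            alphas = 0.05)
  alt <- scenario_spec("normal", case = list(mean = 5),
                       label = "diffM&eqV", n0 = 100, n1 = 100, seed = 52)
  pw <- estimate_power(alt, tests, cuts, n_reps = 200)
  expect_true(all(pw$rate > 0.99))
  expect_error(estimate_power(alt, tests,
                              cuts[cuts$test == "AW", ], n_reps = 10),
               class = "jointDV_invalid_input")   # missing cutoff
  expect_error(estimate_power(null_sp, tests, cuts, n_reps = 10),
               class = "jointDV_invalid_input")   # null label refused
})

test_that("power at the corrected cutoff equals the level under a null-identical alternative", {
  tests <- c("iAW.BF", "jointLRT")
  null_sp <- scenario_spec("normal", n0 = 50, n1 = 50, seed = 61)
  cuts <- corrected_cutoffs(null_statistics(null_sp, tests,
                                            n_reps = 2000),
                            alphas = 0.05)
  # same generating law, label overridden to exercise the power path
  alt <- scenario_spec("normal", case = list(mean = 0),
                       label = "diffM&eqV", n0 = 50, n1 = 50, seed = 62)
  pw <- estimate_power(alt, tests, cuts, n_reps = 2000)
  # both the cutoff and the power estimate carry Monte-Carlo error
  se <- sqrt(2 * 0.05 * 0.95 / 2000)
  expect_true(all(abs(pw$rate - 0.05) < 2 * se))
})
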