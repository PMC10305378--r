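test_that("OLS recovers noiseless coefficients exactly", {
  p <- c(85, 90, 95, 100, 105, 110, 115, 120, 125)
  v <- mk_pwv(p) * 0.9 + 1
  target <- 0.5 + 0.01 * p + 0.9 * v
  m <- fit_mlr(p, v, target)
  expect_equal(m$beta0, 0.5, tolerance = 1e-9)
  expect_equal(m$beta1, 0.01, tolerance = 1e-9)
  expect_equal(m$beta2, 0.9, tolerance = 1e-9)
  expect_lt(m$residual_sd, 1e-9)

  # identity mapping
  mi <- fit_mlr(p, v, v)
  expect_equal(c(mi$beta0, mi$beta1, mi$beta2), c(0, 0, 1), tolerance = 1e-9)

  expect_error(fit_mlr(rep(100, 5), v[1:5], target[1:5]), "p_ref")
  expect_error(fit_mlr(p[1:2], v[1:2], target[1:2]), "at least 3")
})

test_that("noisy OLS coefficients fall within three standard errors", {
  set.seed(77)
  p <- seq(85, 125, length.out = 9)
  v <- mk_pwv(p) * 0.9 + 1
  truth <- c(0.5, 0.01, 0.9)
  target <- truth[1] + truth[2] * p + truth[3] * v + rnorm(9, 0, 0.05)
  m <- fit_mlr(p, v, target)
  se <- summary(m$fit)$coefficients[, "Std. Error"]
  est <- c(m$beta0, m$beta1, m$beta2)
  expect_true(all(abs(est - truth) <= 3 * se))
})

test_that("applying a calibration model is the stated affine map", {
  p <- seq(85, 125, length.out = 9)
  v <- mk_pwv(p)
  ident <- fit_mlr(p, v + rnorm(9, 0, 1e-3), v + rnorm(9, 0, 1e-3))
  expect_equal(apply_calibration(ident, 100, 3),
               ident$beta0 + ident$beta1 * 100 + ident$beta2 * 3)

  # hand-built models: identity and constant
  m1 <- structure(list(beta0 = 0, beta1 = 0, beta2 = 1),
                  class = "calibration_model")
  expect_equal(apply_calibration(m1, 120, 3.3), 3.3)
  m2 <- structure(list(beta0 = 1, beta1 = 0, beta2 = 0),
                  class = "calibration_model")
  expect_equal(apply_calibration(m2, 90, 9.9), 1)
})

test_that("mean absolute error behaves on constructed pairs", {
  expect_equal(mae(1:5, 1:5), 0)
  expect_equal(mae(c(1, 2), c(2, 4)), 1.5)
  x <- runif(20); expect_equal(mae(x, x + 0.78), 0.78)
  expect_error(mae(1:3, 1:4), "length")
})

test_that("Bland-Altman reproduces hand-computed statistics", {
  a <- c(3, 4, 5); b <- a
  ba0 <- bland_altman(a, b)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$diff_sd, 0)

  # pure bias: mean difference equals the offset, zero spread
  ba1 <- bland_altman(a + 0.78, a)
  expect_equal(ba1$mean_diff, 0.78)
  expect_equal(ba1$diff_sd, 0)

  # hand-computed sample sd with n-1 denominator
  ba2 <- bland_altman(c(1.1, 0.9), c(1, 1))
  expect_equal(ba2$mean_diff, 0)
  expect_equal(ba2$diff_sd, sqrt((0.1^2 + 0.1^2) / 1), tolerance = 1e-12)
  expect_equal(ba2$loa_high, 1.96 * ba2$diff_sd)
  expect_equal(ba2$loa_low, -1.96 * ba2$diff_sd)
  expect_equal(ba2$table$mean, c(1.05, 0.95))

  expect_error(bland_altman(1, 1), "2")
})

test_that("1.96-sd limits contain about 95% of Gaussian differences", {
  set.seed(5)
  b <- rnorm(1000); a <- b + rnorm(1000, 0.2, 0.5)
  ba <- bland_altman(a, b)
  inside <- mean(ba$table$diff >= ba$loa_low & ba$table$diff <= ba$loa_high)
  expect_gte(inside, 0.90)
})

test_that("BP error bands shrink with pressure and vanish with the deviation", {
  expect_equal(unname(bp_error_band(0, 100, 180)), c(0, 0))
  for (d in c(0.06, 0.3, 0.77)) {
    band <- bp_error_band(d, 100, 180)
    expect_gt(band["at_p_low"], band["at_p_high"])
  }
  # strictly decreasing in the evaluation pressure
  errs <- vapply(c(100, 120, 150, 180), function(p) {
    unname(bp_error_band(0.5, p, p + 1)["at_p_low"])
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # closed form at one point
  expect_equal(unname(bp_error_band(0.06, 100, 180)["at_p_low"]),
               (2 / 0.031) * log(1 + 0.06 / mk_pwv(100)), tolerance = 1e-9)
})

test_that("the calibration experiment corrects an affine DUT bias", {
  sc <- fast_scenario(dut_bias = list(a = 0.9, b = 1, noise_sd = 0.05))
  rep <- run_calibration_experiment(sc, seed = 42)
  expect_gt(rep$before$mae, 0.5)
  expect_lt(rep$after$mae, 0.1)
  expect_lt(rep$after$mae, rep$before$mae)
  expect_equal(rep$summaries$n_beats, rep(10, 9))

  # unbiased DUT: calibration is close to the identity and changes little
  sc0 <- fast_scenario(dut_bias = list(a = 1, b = 0, noise_sd = 0))
  rep0 <- run_calibration_experiment(sc0, seed = 1)
  expect_lt(rep0$before$mae, 0.2)
  expect_lte(rep0$after$mae, rep0$before$mae + 1e-9)

  # in-sample MAE never increases: OLS optimality on the fitted set
  expect_lte(rep$after$mae, rep$before$mae)
  # limits of agreement bracket the mean difference
  expect_lte(rep$after$loa_low, rep$after$mean_diff)
  expect_gte(rep$after$loa_high, rep$after$mean_diff)
})

test_that("calibration transfers to held-out beats", {
  sc <- fast_scenario(dut_bias = list(a = 0.9, b = 1, noise_sd = 0.05))
  rep <- run_calibration_experiment(sc, seed = 42)
  # apply the fitted model to every accepted beat of a fresh replicate run
  run <- run_setpoint(sc, 5, seed = 999)
  ok <- run$measurements[run$measurements$quality_flag == "ok", ]
  p_ref <- run$summary$p_ref_mmhg
  theory <- mk_pwv(p_ref)
  raw_mae <- mae(ok$pwv_meas, rep(theory, nrow(ok)))
  cal_mae <- mae(apply_calibration(rep$model, p_ref, ok$pwv_meas),
                 rep(theory, nrow(ok)))
  expect_lt(cal_mae, raw_mae)
})

test_that("external device tables calibrate through the same path", {
  p <- seq(85, 125, length.out = 9)
  dev <- data.frame(setpoint_id = 1:9, p_ref_mmhg = p,
                    pwv_mps = 0.95 * mk_pwv(p) + 0.8)
  res <- calibrate_external(dev)
  expect_gt(res$before$mae, 0.3)
  expect_lt(res$after$mae, 0.05)
  expect_named(res$before$bp_error_band, c("at_p_low", "at_p_high"))
})
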