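test_that("pulse pressure and mean arterial pressure follow their formulas", {
  expect_equal(pulse_pressure(120, 80), 40)
  expect_equal(pulse_pressure(100, 100), 0)
  expect_equal(pulse_pressure(160, 60), 100)
  expect_error(pulse_pressure(80, 120), "sbp")

  expect_equal(mean_arterial_pressure(120, 80), 120 / 3 + 160 / 3)
  expect_equal(mean_arterial_pressure(90, 90), 90)
  expect_equal(mean_arterial_pressure(150, 75), 100)
  expect_error(mean_arterial_pressure(70, 90), "sbp")

  # MAP always sits between DBP and SBP
  sbp <- runif(50, 100, 180); dbp <- runif(50, 60, 100)
  sbp <- pmax(sbp, dbp)
  m <- mean_arterial_pressure(sbp, dbp)
  expect_true(all(m >= dbp - 1e-12 & m <= sbp + 1e-12))
})

test_that("windowed RMS reference pressure matches closed forms", {
  # RMS of a constant equals the constant exactly, one value per window
  s <- pressure_series(rep(100, 500), fs = 250)
  expect_identical(rms_reference_map(s), c(100, 100))

  # offset sinusoid with whole cycles per window: sqrt(m^2 + a^2/2)
  fs <- 200; tt <- (0:(8 * fs - 1)) / fs
  s2 <- pressure_series(100 + 10 * sin(2 * pi * 1.25 * tt), fs = fs)
  expect_equal(rms_reference_map(s2, window_s = 8), sqrt(100^2 + 10^2 / 2),
               tolerance = 1e-9)

  # 2 s trace, 1 s windows -> exactly 2 values
  expect_length(rms_reference_map(pressure_series(rnorm(400) + 50, fs = 200)), 2)
  expect_error(rms_reference_map(pressure_series(1, fs = 1), window_s = 2),
               "window")
})

test_that("Young's modulus is E0 at zero pressure and grows exponentially", {
  expect_equal(young_modulus(0), 1428.7)
  expect_equal(young_modulus(100), 1428.7 * exp(3.1))
  expect_gt(young_modulus(120), young_modulus(100))
})

test_that("Moens-Korteweg PWV: values, monotonicity and scaling", {
  expect_equal(mk_pwv(0), sqrt(1428.7 * 0.25 / 1000), tolerance = 1e-12)
  expect_equal(mk_pwv(100), sqrt(1428.7 * exp(3.1) * 0.25 / 1000),
               tolerance = 1e-12)
  expect_equal(mk_pwv(100), 2.8158, tolerance = 1e-4)

  # strictly increasing at 100 random pressures
  p <- sort(runif(100, 0, 300))
  expect_true(all(diff(mk_pwv(p)) > 0))

  # doubling the density divides PWV by sqrt(2)
  heavy <- tube_params(fluid_density = 2000)
  expect_equal(mk_pwv(50, heavy), mk_pwv(50) / sqrt(2), tolerance = 1e-12)
})

test_that("Bramwell-Hill PWV scales as sqrt(dP) and inverts algebraically", {
  # identity construction: choose dV so that V*dP/(rho*dV) = 1 in SI
  dv <- 133.322 / 1000   # V = 1 mL, dP = 1 mmHg, rho = 1000
  expect_equal(bh_pwv(1, 1, dv), 1)
  # quadrupling dP doubles PWV
  expect_equal(bh_pwv(1, 4, dv), 2)
  # round trip: dV computed from a chosen PWV feeds back to that PWV
  target <- 3.7
  dv2 <- 1 * 133.322 * 2 / (1000 * target^2)
  expect_equal(bh_pwv(1, 2, dv2), target, tolerance = 1e-12)
  expect_error(bh_pwv(1, 1, 0), "dV")
})

test_that("Bramwell-Hill agrees with Moens-Korteweg in the small-increment limit", {
  for (P in c(50, 100, 150, 250)) {
    dP <- 1e-4
    # compliance dV/dP = V / (rho * pwv^2) evaluated at the midpoint pressure
    pwv_mid <- mk_pwv(P + dP / 2)
    dV <- 1 * 133.322 * dP / (1000 * pwv_mid^2)
    expect_equal(bh_pwv(1, dP, dV), mk_pwv(P), tolerance = 1e-6)
  }
})

test_that("invert_mk is the exact inverse of mk_pwv", {
  p <- seq(0, 300, length.out = 61)
  expect_equal(invert_mk(mk_pwv(p)), p, tolerance = 1e-9)
  expect_equal(invert_mk(mk_pwv(0)), 0, tolerance = 1e-9)
  expect_equal(invert_mk(2.8158), 100, tolerance = 1e-3)
  # strictly increasing in pwv
  v <- sort(runif(100, 0.5, 12))
  expect_true(all(diff(invert_mk(v)) > 0))
  expect_error(invert_mk(-1), "pwv")
})

test_that("PWV from transit time follows L/PTT", {
  expect_equal(pwv_from_ptt(20, L = 4), 2)
  expect_equal(pwv_from_ptt(4, L = 4), 10)
  expect_equal(pwv_from_ptt(10, L = 4), 2 * pwv_from_ptt(20, L = 4))
  expect_error(pwv_from_ptt(0), "ptt")
  expect_error(pwv_from_ptt(-3), "ptt")
})

test_that("BP error propagation follows the log form and its symmetries", {
  expect_equal(bp_error_from_pwv_error(3, 0), 0)
  # closed form matches the numerical difference of invert_mk
  for (case in list(c(2.8158, 0.77), c(4, -0.5), c(2, 0.06))) {
    pwv <- case[1]; d <- case[2]
    expect_equal(bp_error_from_pwv_error(pwv, d),
                 invert_mk(pwv + d) - invert_mk(pwv), tolerance = 1e-9)
    # antisymmetry: error(pwv, d) = -error(pwv + d, -d)
    expect_equal(bp_error_from_pwv_error(pwv, d),
                 -bp_error_from_pwv_error(pwv + d, -d), tolerance = 1e-12)
  }
  expect_equal(bp_error_from_pwv_error(2.8158, 0.77),
               (2 / 0.031) * log(1 + 0.77 / 2.8158), tolerance = 1e-12)
  # magnitude decreases as the operating PWV grows
  errs <- abs(bp_error_from_pwv_error(c(2, 4, 8), 0.5))
  expect_true(all(diff(errs) < 0))
  expect_error(bp_error_from_pwv_error(1, -1), "pwv")
})
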