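#' Pulse pressure
#'
#' `PP = SBP - DBP`, the pressure swing produced by each pump stroke.
#'
#' @param sbp Systolic pressure, mmHg.
#' @param dbp Diastolic pressure, mmHg.  Must not exceed `sbp`.
#' @return Pulse pressure, mmHg.
#' @examples
#' pulse_pressure(120, 80)
#' @export
pulse_pressure <- function(sbp, dbp) {
  stop_if(any(sbp < dbp), "'sbp' must be >= 'dbp'")
  sbp - dbp
}

#' Mean arterial pressure
#'
#' The standard clinical estimate `MAP = SBP/3 + 2*DBP/3`: the mean is
#' weighted towards diastole because diastole occupies roughly two thirds of
#' the cardiac cycle.
#'
#' @inheritParams pulse_pressure
#' @return Mean arterial pressure, mmHg.
#' @examples
#' mean_arterial_pressure(120, 80)
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  stop_if(any(sbp < dbp), "'sbp' must be >= 'dbp'")
  sbp / 3 + 2 * dbp / 3
}

#' Windowed RMS reference pressure
#'
#' The simulator's reference MAP is taken as the root-mean-square of the
#' pressure-sensor trace over consecutive non-overlapping windows (1 s by
#' default), one value per window.
#'
#' @param series A [pressure_series()] of raw pressure in mmHg.
#' @param window_s Window length, s.
#' @return Numeric vector of one RMS value per complete window, in
#'   acquisition order.
#' @examples
#' s <- pressure_series(rep(100, 500), fs = 250)
#' rms_reference_map(s)   # 100 100
#' @export
rms_reference_map <- function(series, window_s = 1) {
  stopifnot(inherits(series, "pressure_series"))
  check_scalar(window_s, "window_s")
  n_win <- floor(window_s * series$fs + 1e-9)
  stop_if(n_win < 1, "'window_s' is shorter than one sample period")
  n <- length(series$samples)
  k <- n %/% n_win
  stop_if(k < 1, "series shorter than one window")
  x <- series$samples[seq_len(k * n_win)]
  m <- matrix(x * x, nrow = n_win)
  sqrt(colMeans(m))
}

#' Pressure-dependent wall Young's modulus
#'
#' `E(P) = E0 * exp(gamma * P)`: the tube wall stiffens exponentially with
#' distending pressure.  P may be any real number; simulator-level validation
#' rejects negative operating pressures.
#'
#' @param P Internal pressure, mmHg (vectorised).
#' @param tube A [tube_params()] object.
#' @return Young's modulus, Pa.
#' @examples
#' young_modulus(0)    # E0 = 1428.7 Pa
#' young_modulus(100)
#' @export
young_modulus <- function(P, tube = tube_params()) {
  stopifnot(inherits(tube, "tube_params"))
  tube$modulus_zero * exp(tube$stiffness_coeff * P)
}

#' Moens-Korteweg pulse wave velocity
#'
#' `PWV = sqrt(E(P) * h / (D * rho))` for a thin-walled elastic tube of wall
#' thickness h, inner diameter D, wall modulus E and fluid density rho.  With
#' the exponential modulus of [young_modulus()] this gives the theoretical
#' PWV-pressure curve of the phantom; it is strictly increasing in P.
#'
#' @inheritParams young_modulus
#' @return Pulse wave velocity, m/s.
#' @examples
#' mk_pwv(c(100, 140, 180))
#' @export
mk_pwv <- function(P, tube = tube_params()) {
  stopifnot(inherits(tube, "tube_params"))
  E <- young_modulus(P, tube)
  h <- mm_to_m(tube$wall_thickness)
  D <- mm_to_m(tube$inner_diameter)
  sqrt(E * h / (D * tube$fluid_density))
}

#' Bramwell-Hill pulse wave velocity
#'
#' `PWV = sqrt(V * dP / (rho * dV))`: the wave speed expressed through the
#' pressure-volume compliance of a vessel segment of initial volume V.  For a
#' volume increment consistent with the Moens-Korteweg compliance this agrees
#' with [mk_pwv()] in the small-increment limit.
#'
#' @param V Initial segment volume, mL.
#' @param dP Pressure increment, mmHg.
#' @param dV Volume increment, mL.  Must be positive.
#' @param rho Fluid density, kg/m^3.
#' @return Pulse wave velocity, m/s.
#' @examples
#' bh_pwv(V = 1, dP = 1, dV = 0.01)
#' @export
bh_pwv <- function(V, dP, dV, rho = 1000) {
  check_scalar(V, "V")
  check_scalar(dP, "dP")
  check_scalar(rho, "rho")
  stop_if(!is.numeric(dV) || length(dV) != 1L || is.na(dV) || dV <= 0,
          "'dV' must be strictly positive")
  # mL cancels in V/dV; dP to Pa for SI speed
  sqrt(V * mmhg_to_pa(dP) / (rho * dV))
}

#' Invert the Moens-Korteweg curve: pressure from PWV
#'
#' Solves `pwv = mk_pwv(P)` for P:
#' `P = (1/gamma) * ln(pwv^2 * D * rho / (E0 * h))` (with SI conversion of
#' D, h, rho and pwv).  Exact inverse of [mk_pwv()].
#'
#' @param pwv Pulse wave velocity, m/s (vectorised, strictly positive).
#' @param tube A [tube_params()] object.
#' @return Pressure, mmHg.
#' @examples
#' invert_mk(mk_pwv(100))   # 100
#' @export
invert_mk <- function(pwv, tube = tube_params()) {
  stopifnot(inherits(tube, "tube_params"))
  stop_if(any(!is.finite(pwv)) || any(pwv <= 0), "'pwv' must be > 0")
  h <- mm_to_m(tube$wall_thickness)
  D <- mm_to_m(tube$inner_diameter)
  log(pwv^2 * D * tube$fluid_density / (tube$modulus_zero * h)) /
    tube$stiffness_coeff
}

#' Pulse wave velocity from transit time
#'
#' `PWV = L / PTT` for sensor spacing L.
#'
#' @param ptt Pulse transit time, ms (vectorised, strictly positive).
#' @param L Sensor distance, cm.
#' @return PWV, m/s.
#' @examples
#' pwv_from_ptt(20, L = 4)   # 2 m/s
#' @export
pwv_from_ptt <- function(ptt, L = 4) {
  check_scalar(L, "L")
  stop_if(any(!is.finite(ptt)) || any(ptt <= 0),
          "'ptt' must be > 0 (non-positive transit time signals failed peak pairing)")
  cm_to_m(L) / ms_to_s(ptt)
}

#' Blood-pressure error caused by a PWV measurement error
#'
#' Propagates a PWV deviation through the inverse Moens-Korteweg curve:
#' `dP = invert_mk(pwv + dpwv) - invert_mk(pwv) = (2/gamma) * ln(1 + dpwv/pwv)`.
#' For a fixed deviation the resulting BP error is larger at slower PWV
#' (lower pressure), since the curve flattens there.
#'
#' @param pwv Operating pulse wave velocity, m/s.
#' @param dpwv PWV deviation, m/s.  `pwv + dpwv` must stay positive.
#' @param tube A [tube_params()] object.
#' @return Blood-pressure error, mmHg (signed).
#' @examples
#' bp_error_from_pwv_error(2.8, 0.77)
#' @export
bp_error_from_pwv_error <- function(pwv, dpwv, tube = tube_params()) {
  stopifnot(inherits(tube, "tube_params"))
  stop_if(any(pwv <= 0), "'pwv' must be > 0")
  stop_if(any(pwv + dpwv <= 0), "'pwv + dpwv' must be > 0")
  (2 / tube$stiffness_coeff) * log1p(dpwv / pwv)
}
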