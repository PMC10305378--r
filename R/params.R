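#' Arterial phantom tube parameters
#'
#' Geometry, material and fluid constants of the elastic tube that acts as
#' the arterial phantom, plus the sensor spacing of the device under test.
#' Defaults describe a silicone-rubber radial-artery phantom: 4 mm inner
#' diameter, 1 mm wall, water as the circulating fluid, and a wall Young's
#' modulus following `E(P) = E0 * exp(gamma * P)` with brachial-artery
#' literature values `E0 = 1428.7` (Pa) and `gamma = 0.031` (per mmHg).
#'
#' @param inner_diameter Inner diameter D of the tube, mm.
#' @param wall_thickness Wall thickness h, mm. Must be smaller than D.
#' @param fluid_density Fluid density rho, kg/m^3. Water (1000) by default;
#'   use 1060 for whole blood.
#' @param modulus_zero Elastic modulus at zero pressure E0, Pa.
#' @param stiffness_coeff Exponential stiffness coefficient gamma, per mmHg.
#' @param sensor_distance Distance L between the two DUT sensors, cm.
#' @return An object of class `tube_params`.
#' @examples
#' tube <- tube_params()
#' mk_pwv(100, tube)
#' @export
tube_params <- function(inner_diameter = 4,
                        wall_thickness = 1,
                        fluid_density = 1000,
                        modulus_zero = 1428.7,
                        stiffness_coeff = 0.031,
                        sensor_distance = 4) {
  check_scalar(inner_diameter, "inner_diameter")
  check_scalar(wall_thickness, "wall_thickness")
  check_scalar(fluid_density, "fluid_density")
  check_scalar(modulus_zero, "modulus_zero")
  check_scalar(stiffness_coeff, "stiffness_coeff")
  check_scalar(sensor_distance, "sensor_distance")
  stop_if(wall_thickness >= inner_diameter,
          "'wall_thickness' must be smaller than 'inner_diameter'")
  structure(
    list(inner_diameter = inner_diameter,
         wall_thickness = wall_thickness,
         fluid_density = fluid_density,
         modulus_zero = modulus_zero,
         stiffness_coeff = stiffness_coeff,
         sensor_distance = sensor_distance),
    class = "tube_params")
}

#' @export
print.tube_params <- function(x, ...) {
  cat("Arterial phantom tube parameters\n")
  cat(sprintf("  inner diameter D : %g mm\n", x$inner_diameter))
  cat(sprintf("  wall thickness h : %g mm\n", x$wall_thickness))
  cat(sprintf("  fluid density    : %g kg/m^3\n", x$fluid_density))
  cat(sprintf("  E0 (P = 0)       : %g Pa\n", x$modulus_zero))
  cat(sprintf("  gamma            : %g /mmHg\n", x$stiffness_coeff))
  cat(sprintf("  sensor distance L: %g cm\n", x$sensor_distance))
  invisible(x)
}

#' Pulsatile pump parameters
#'
#' Parameters of the electric pump that plays the role of the heart in the
#' simulator.  The pump is driven by a PWM signal; its duty cycle controls
#' the pulse pressure through an affine map with a dead zone
#' (`PP = pp_per_duty * max(0, duty - duty_min)`).  The mapping is a
#' package calibration chosen so that duty cycles 0.26-0.90 over an 80 mmHg
#' base pressure span systolic pressures of 100-180 mmHg; it is monotone, as
#' required of the physical pump, but is not an empirical pump curve.
#'
#' @param pp_per_duty Pulse pressure gained per unit duty cycle above the
#'   dead zone, mmHg.
#' @param duty_min Dead-zone duty cycle below which the pump builds no pulse
#'   pressure, fraction in \[0, 1).
#' @param heart_rate Pump repetition rate, beats per minute.  75 bpm
#'   corresponds to a 1.25 Hz pulse frequency; 1 Hz gives 60 bpm.
#' @param systolic_fraction Fraction of the beat period spent in the systolic
#'   phase (upstroke plus systolic decay).
#' @return An object of class `pump_params`.
#' @examples
#' pump_params(heart_rate = 75)
#' @export
pump_params <- function(pp_per_duty = 125,
                        duty_min = 0.1,
                        heart_rate = 75,
                        systolic_fraction = 0.35) {
  check_scalar(pp_per_duty, "pp_per_duty")
  check_scalar(duty_min, "duty_min", positive = FALSE)
  stop_if(duty_min < 0 || duty_min >= 1, "'duty_min' must be in [0, 1)")
  check_scalar(heart_rate, "heart_rate")
  check_scalar(systolic_fraction, "systolic_fraction")
  stop_if(systolic_fraction >= 1, "'systolic_fraction' must be in (0, 1)")
  structure(
    list(pp_per_duty = pp_per_duty,
         duty_min = duty_min,
         heart_rate = heart_rate,
         systolic_fraction = systolic_fraction),
    class = "pump_params")
}

#' @export
print.pump_params <- function(x, ...) {
  cat("Pulsatile pump parameters\n")
  cat(sprintf("  PP per duty      : %g mmHg\n", x$pp_per_duty))
  cat(sprintf("  duty dead zone   : %g\n", x$duty_min))
  cat(sprintf("  heart rate       : %g bpm (%.3g Hz)\n",
              x$heart_rate, x$heart_rate / 60))
  cat(sprintf("  systolic fraction: %g\n", x$systolic_fraction))
  invisible(x)
}

#' Reflected-wave parameters
#'
#' The pressure pulse reflects at the distal tube turn and travels back with
#' its transverse displacement reversed (a 180 degree phase inversion).  The
#' reflection is modelled as a delayed, scaled, optionally inverted copy of
#' the pulsatile component.  By default the delay is derived at synthesis
#' time as the round trip from the measurement site to the turn,
#' `2 * site_distance / PWV(MAP)`, with the site 2 cm before the turn.
#'
#' @param amplitude_ratio Amplitude of the reflected wave relative to the
#'   primary pulse, fraction in \[0, 1).  Must stay below 1 so the reflected
#'   peak's gradient remains smaller than the primary upstroke's.
#' @param inverted Logical; reflected displacement reversed (default TRUE).
#' @param reflection_delay Explicit delay in seconds, or `NULL` to derive it
#'   from `site_distance` and the operating PWV.
#' @param site_distance Distance from the sensing site to the reflection
#'   site (the tube turn), cm.
#' @return An object of class `reflection_params`.
#' @export
reflection_params <- function(amplitude_ratio = 0.3,
                              inverted = TRUE,
                              reflection_delay = NULL,
                              site_distance = 2) {
  check_scalar(amplitude_ratio, "amplitude_ratio", positive = FALSE)
  stop_if(amplitude_ratio < 0 || amplitude_ratio >= 1,
          "'amplitude_ratio' must be in [0, 1)")
  stop_if(!is.logical(inverted) || length(inverted) != 1L || is.na(inverted),
          "'inverted' must be TRUE or FALSE")
  if (!is.null(reflection_delay)) check_scalar(reflection_delay, "reflection_delay")
  check_scalar(site_distance, "site_distance")
  structure(
    list(amplitude_ratio = amplitude_ratio,
         inverted = inverted,
         reflection_delay = reflection_delay,
         site_distance = site_distance),
    class = "reflection_params")
}

#' @export
print.reflection_params <- function(x, ...) {
  cat("Reflected-wave parameters\n")
  cat(sprintf("  amplitude ratio : %g\n", x$amplitude_ratio))
  cat(sprintf("  inverted        : %s\n", x$inverted))
  cat(sprintf("  delay           : %s\n",
              if (is.null(x$reflection_delay)) {
                sprintf("auto (round trip over %g cm)", x$site_distance)
              } else sprintf("%g s", x$reflection_delay)))
  invisible(x)
}

#' DUT acquisition-chain parameters
#'
#' The device under test samples two piezoelectric sensors at 5 kHz through
#' an analog front end band-passing 0.6-10.6 Hz, then applies a digital FIR
#' band-pass of 0.7-9.5 Hz.  Filters are linear-phase windowed-sinc FIRs
#' applied with zero phase so that the inter-sensor delay is preserved.
#'
#' The default FIR length (16385 taps at 5 kHz, about 1 Hz transition width)
#' is what a sub-hertz cutoff at this sampling rate requires; shorter filters
#' cannot separate the 0.6-0.7 Hz high-pass edges from DC.  For traces
#' shorter than the filter the length is reduced to fit.
#'
#' @param fs Sampling rate, Hz.
#' @param analog_band Analog front-end band edges c(low, high), Hz.
#' @param digital_band Digital FIR band edges c(low, high), Hz.
#' @param fir_taps FIR length (odd number of taps).
#' @param noise_sd Additive white Gaussian noise standard deviation, in
#'   pressure-equivalent units, applied per channel after filtering.
#' @param seed Integer seed for the noise stream, or `NULL`.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(fs = 5000,
                               analog_band = c(0.6, 10.6),
                               digital_band = c(0.7, 9.5),
                               fir_taps = 16385,
                               noise_sd = 0,
                               seed = NULL) {
  check_scalar(fs, "fs")
  check_band <- function(band, name) {
    stop_if(!is.numeric(band) || length(band) != 2L || any(is.na(band)),
            sprintf("'%s' must be c(low, high) in Hz", name))
    stop_if(band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2,
            sprintf("'%s' must satisfy 0 < low < high < fs/2", name))
  }
  check_band(analog_band, "analog_band")
  check_band(digital_band, "digital_band")
  check_scalar(fir_taps, "fir_taps")
  stop_if(fir_taps < 3, "'fir_taps' must be at least 3")
  check_scalar(noise_sd, "noise_sd", positive = FALSE)
  stop_if(noise_sd < 0, "'noise_sd' must be non-negative")
  if (!is.null(seed)) check_scalar(seed, "seed", positive = FALSE)
  structure(
    list(fs = fs,
         analog_band = as.numeric(analog_band),
         digital_band = as.numeric(digital_band),
         fir_taps = as.integer(fir_taps),
         noise_sd = noise_sd,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("DUT acquisition parameters\n")
  cat(sprintf("  sampling rate : %g Hz (%.3g ms per sample)\n",
              x$fs, 1000 / x$fs))
  cat(sprintf("  analog band   : %g-%g Hz\n", x$analog_band[1], x$analog_band[2]))
  cat(sprintf("  digital band  : %g-%g Hz (FIR, %d taps)\n",
              x$digital_band[1], x$digital_band[2], x$fir_taps))
  cat(sprintf("  noise sd      : %g\n", x$noise_sd))
  invisible(x)
}
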