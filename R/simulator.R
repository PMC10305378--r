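#' Pressure setpoint
#'
#' One operating point of the simulator: base (diastolic) pressure, pump
#' duty cycle, and the resulting SBP/DBP/PP/MAP.  Usually constructed via
#' [duty_to_setpoint()].
#'
#' @param sbp,dbp Systolic and diastolic pressure, mmHg.
#' @param base_pressure Static base pressure of the circuit, mmHg
#'   (defaults to `dbp`).
#' @param duty_cycle Pump PWM duty cycle in \[0, 1\], or `NA` if unknown.
#' @return An object of class `pressure_setpoint` with fields `sbp`, `dbp`,
#'   `pp`, `map`, `base_pressure`, `duty_cycle`.
#' @export
pressure_setpoint <- function(sbp, dbp, base_pressure = dbp, duty_cycle = NA_real_) {
  check_scalar(sbp, "sbp")
  check_scalar(dbp, "dbp")
  stop_if(sbp < dbp, "'sbp' must be >= 'dbp'")
  check_scalar(base_pressure, "base_pressure")
  if (!is.na(duty_cycle)) {
    stop_if(duty_cycle < 0 || duty_cycle > 1, "'duty_cycle' must be in [0, 1]")
  }
  structure(
    list(sbp = sbp, dbp = dbp,
         pp = pulse_pressure(sbp, dbp),
         map = mean_arterial_pressure(sbp, dbp),
         base_pressure = base_pressure,
         duty_cycle = duty_cycle),
    class = "pressure_setpoint")
}

#' @export
print.pressure_setpoint <- function(x, ...) {
  cat(sprintf(
    "Setpoint: SBP %g / DBP %g mmHg (PP %g, MAP %.5g), base %g mmHg, duty %s\n",
    x$sbp, x$dbp, x$pp, x$map, x$base_pressure,
    if (is.na(x$duty_cycle)) "-" else format(x$duty_cycle)))
  invisible(x)
}

#' Map a pump duty cycle to a pressure setpoint
#'
#' The diastolic pressure stays at the circuit's base pressure; the pulse
#' pressure grows affinely with duty cycle above the pump's dead zone
#' (`PP = pp_per_duty * max(0, duty - duty_min)`), so PP, SBP and MAP are
#' all non-decreasing in duty.
#'
#' @param duty Pump duty cycle, fraction in \[0, 1\].
#' @param base_pressure Base pressure, mmHg.
#' @param pump A [pump_params()] object.
#' @return A [pressure_setpoint()].
#' @examples
#' duty_to_setpoint(0.5, 80)
#' @export
duty_to_setpoint <- function(duty, base_pressure, pump = pump_params()) {
  stopifnot(inherits(pump, "pump_params"))
  check_scalar(duty, "duty", positive = FALSE)
  stop_if(duty < 0 || duty > 1, "'duty' must be in [0, 1]")
  check_scalar(base_pressure, "base_pressure")
  pp <- pump$pp_per_duty * max(0, duty - pump$duty_min)
  pressure_setpoint(sbp = base_pressure + pp, dbp = base_pressure,
                    base_pressure = base_pressure, duty_cycle = duty)
}

# Internal: pulsatile beat template on [0, 1) normalized time, amplitude in
# [0, 1].  Raised-cosine upstroke to the systolic peak over the first 40% of
# the systolic phase, cosine decay to a shoulder, then exponential
# relaxation towards the diastolic baseline.
beat_template <- function(phase, systolic_fraction,
                          shoulder = 0.3, tau_frac = 1 / 6) {
  t_up <- 0.4 * systolic_fraction
  t_sys <- systolic_fraction
  y <- numeric(length(phase))
  up <- phase < t_up
  y[up] <- (1 - cos(pi * phase[up] / t_up)) / 2
  dec <- phase >= t_up & phase < t_sys
  y[dec] <- shoulder + (1 - shoulder) *
    (1 + cos(pi * (phase[dec] - t_up) / (t_sys - t_up))) / 2
  dia <- phase >= t_sys
  tau <- tau_frac * (1 - t_sys)
  y[dia] <- shoulder * exp(-(phase[dia] - t_sys) / tau)
  y
}

#' Synthesize one beat of the phantom pressure waveform
#'
#' Generates a single beat of length `60 / heart_rate` seconds on the
#' sampling grid: a steep raised-cosine upstroke from DBP to the systolic
#' peak, a cosine decay to a systolic shoulder, and an exponential
#' relaxation back to DBP.  The peak equals the setpoint's SBP and the
#' trough its DBP (to well within 0.5%), and the upstroke is the single
#' dominant-gradient feature, as required by first-peak detection.
#'
#' @param setpoint A [pressure_setpoint()].
#' @param pump A [pump_params()] (heart rate and systolic fraction).
#' @param fs Sampling rate, Hz (at least 100).
#' @return A [pressure_series()] of one beat, mmHg.
#' @examples
#' b <- synth_beat(pressure_setpoint(120, 80), pump_params(), fs = 5000)
#' range(b$samples)
#' @export
synth_beat <- function(setpoint, pump = pump_params(), fs = 5000) {
  stopifnot(inherits(setpoint, "pressure_setpoint"), inherits(pump, "pump_params"))
  check_scalar(fs, "fs")
  stop_if(fs < 100, "'fs' must be at least 100 Hz to resolve the upstroke")
  period <- 60 / pump$heart_rate
  n <- round(fs * period)
  stop_if(n < 10, "sampling rate too low for this heart rate")
  phase <- (seq_len(n) - 1) / n
  y <- setpoint$dbp +
    setpoint$pp * beat_template(phase, pump$systolic_fraction)
  pressure_series(y, fs = fs, label = "phantom_pressure")
}

#' Superpose a reflected wave on a pressure trace
#'
#' Adds a delayed, scaled and (by default) inverted copy of the pulsatile
#' component: `out = x + amplitude_ratio * s * shift(x - baseline, delay)`
#' with `s = -1` when inverted.  Because `amplitude_ratio < 1`, the
#' reflected feature's maximum absolute gradient stays below the primary
#' upstroke's, which is what lets the DUT's first-peak detector reject it.
#'
#' @param beat A [pressure_series()] (one beat or a concatenated trace), mmHg.
#' @param refl A [reflection_params()].  If its `reflection_delay` is `NULL`,
#'   pass an explicit `delay_s`.
#' @param delay_s Reflection delay override, s.
#' @param baseline Diastolic baseline defining the pulsatile component;
#'   defaults to `min(beat$samples)`.
#' @return A [pressure_series()] with the reflection added.
#' @export
add_reflected_wave <- function(beat, refl = reflection_params(),
                               delay_s = NULL, baseline = NULL) {
  stopifnot(inherits(beat, "pressure_series"), inherits(refl, "reflection_params"))
  delay <- if (!is.null(delay_s)) delay_s else refl$reflection_delay
  stop_if(is.null(delay),
          "reflection delay not set: give 'delay_s' or a 'reflection_delay'")
  check_scalar(delay, "delay_s")
  stop_if(delay >= series_duration(beat),
          "reflection delay must be shorter than the trace")
  if (refl$amplitude_ratio == 0) return(beat)
  if (is.null(baseline)) baseline <- min(beat$samples)
  puls <- beat$samples - baseline
  shifted <- frac_delay_shift(puls, delay * beat$fs, pad = 0)
  sgn <- if (refl$inverted) -1 else 1
  series_with(beat, beat$samples + refl$amplitude_ratio * sgn * shifted)
}

# Internal: reflection delay as the round trip from the sensing site to the
# tube turn at the Moens-Korteweg speed for the operating MAP.
resolve_reflection_delay <- function(refl, setpoint, tube) {
  if (!is.null(refl$reflection_delay)) return(refl$reflection_delay)
  2 * cm_to_m(refl$site_distance) / mk_pwv(setpoint$map, tube)
}

#' Synthesize a multi-beat phantom pressure trace
#'
#' Concatenates beats at the pump's heart rate over the requested duration
#' and applies the reflected wave.  The number of complete beats is
#' `floor(duration * heart_rate / 60)`; a trailing partial beat fills the
#' remaining samples.  Optional Gaussian beat-period jitter (off by default:
#' the physical pump is strictly periodic) is seeded and reproducible.
#'
#' @param setpoint A [pressure_setpoint()].
#' @param pump A [pump_params()].
#' @param refl A [reflection_params()], or `NULL` for no reflection.
#' @param duration Trace duration, s (longer than one beat period).
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed used when `jitter_sd > 0`.
#' @param tube A [tube_params()], used to derive the default reflection delay.
#' @param jitter_sd Standard deviation of the per-beat period jitter, s.
#' @return A [pressure_series()], mmHg.
#' @examples
#' s <- synth_pressure_series(duty_to_setpoint(0.4, 80), duration = 2, fs = 1000)
#' @export
synth_pressure_series <- function(setpoint, pump = pump_params(),
                                  refl = reflection_params(),
                                  duration = 60, fs = 5000, seed = NULL,
                                  tube = tube_params(), jitter_sd = 0) {
  stopifnot(inherits(setpoint, "pressure_setpoint"), inherits(pump, "pump_params"))
  check_scalar(duration, "duration")
  period <- 60 / pump$heart_rate
  stop_if(duration <= period, "'duration' must exceed one beat period")
  stop_if(setpoint$dbp <= 0, "operating pressures must be positive")
  n_total <- round(duration * fs)
  n_beats <- floor(duration * pump$heart_rate / 60 + 1e-9)

  if (jitter_sd > 0) {
    stop_if(is.null(seed), "'seed' is required when jitter_sd > 0")
    set.seed(as.integer(seed))
    periods <- pmax(0.5 * period, rnorm(n_beats + 2, period, jitter_sd))
  } else {
    periods <- rep(period, n_beats + 2)
  }
  pieces <- lapply(periods, function(p) {
    n <- round(fs * p)
    phase <- (seq_len(n) - 1) / n
    setpoint$dbp + setpoint$pp * beat_template(phase, pump$systolic_fraction)
  })
  y <- unlist(pieces, use.names = FALSE)[seq_len(n_total)]
  out <- pressure_series(y, fs = fs, label = "phantom_pressure")
  if (!is.null(refl) && refl$amplitude_ratio > 0) {
    delay <- resolve_reflection_delay(refl, setpoint, tube)
    out <- add_reflected_wave(out, refl, delay_s = delay, baseline = setpoint$dbp)
  }
  attr(out, "setpoint") <- setpoint
  attr(out, "n_beats") <- n_beats
  out
}
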