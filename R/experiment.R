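# End-to-end calibration experiment: simulate every setpoint, acquire and
# measure it with the DUT model, fit the MLR calibration on per-setpoint
# medians, and report before/after agreement statistics.

#' Simulate and measure a single setpoint
#'
#' Runs one operating point through the whole chain: setpoint synthesis with
#' reflection, propagation past the two sensors at the Moens-Korteweg speed
#' for the operating pressure, acquisition filtering and noise, first-peak
#' detection and per-beat PTT/PWV, then the DUT bias model applied to the
#' per-beat estimates.  The operating pressure is the windowed-RMS reference
#' pressure of the synthesized trace — the same convention the reference
#' sensor reports — so an unbiased DUT measures the theoretical curve.
#'
#' @param scenario A [scenario_config()].
#' @param index Row of `scenario$setpoints` to run.
#' @param seed Substream seed for this setpoint.
#' @return A list with `setpoint`, `true_pwv` (m/s), `measurements`
#'   (per-beat data frame including biased `pwv_meas`) and `summary`
#'   (one-row data frame from [summarize_setpoint()], PWV statistics taken
#'   over the biased measurements).
#' @export
run_setpoint <- function(scenario, index, seed = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  row <- scenario$setpoints[index, ]
  if (is.null(seed)) seed <- derive_seed(scenario$seed, 100 + index)
  sp <- duty_to_setpoint(row$duty, row$base_pressure, scenario$pump)
  raw <- synth_pressure_series(sp, scenario$pump, scenario$refl,
                               duration = scenario$duration_s,
                               fs = scenario$acq$fs,
                               seed = derive_seed(seed, 1),
                               tube = scenario$tube)
  p_ref <- mean(rms_reference_map(raw))
  true_pwv <- mk_pwv(p_ref, scenario$tube)
  rec <- propagate(raw, true_pwv, L = scenario$tube$sensor_distance,
                   meta = list(setpoint = unclass(sp)))
  acq <- scenario$acq
  acq$seed <- derive_seed(seed, 2)
  rec <- acquire(rec, acq)
  meas <- measure_record(rec, hr_hint = scenario$pump$heart_rate,
                         L = scenario$tube$sensor_distance)

  bias <- scenario$dut_bias
  ok <- meas$quality_flag == "ok"
  noise <- if (bias$noise_sd > 0) {
    set.seed(derive_seed(seed, 3))
    rnorm(sum(ok), 0, bias$noise_sd)
  } else 0
  meas$pwv_meas <- NA_real_
  meas$pwv_meas[ok] <- bias$a * meas$pwv_mps[ok] + bias$b + noise

  biased <- meas
  biased$pwv_mps <- biased$pwv_meas
  list(setpoint = sp,
       true_pwv = true_pwv,
       measurements = meas,
       summary = summarize_setpoint(biased, raw, setpoint_id = index))
}

#' Run the full calibration experiment
#'
#' Simulates every setpoint of the scenario, summarises the DUT's per-beat
#' PWV at each, fits the MLR calibration on the per-setpoint medians against
#' the theoretical Moens-Korteweg PWV at the measured reference pressure,
#' and reports agreement statistics before and after calibration: mean
#' absolute error, Bland-Altman mean difference / sd / limits of agreement,
#' and the blood-pressure error band implied by each MAE over the evaluated
#' pressure range.
#'
#' @param scenario A [scenario_config()].
#' @param seed Master seed override (defaults to `scenario$seed`).
#' @param fit_on `"medians"` (default: one point per setpoint) or
#'   `"beats"` (every accepted beat).
#' @param bp_range Pressure range over which the BP error bands are
#'   evaluated, mmHg.
#' @return An object of class `calibration_report`: a list with
#'   `summaries` (per-setpoint table), `model` (the [fit_mlr()] fit),
#'   `before` / `after` (each with `mae`, Bland-Altman statistics and
#'   `bp_error_band`), and `provenance` (seed, scenario, package version).
#' @examples
#' \donttest{
#' sc <- scenario_config(duration_s = 8,
#'                       acq = acquisition_params(fs = 1000),
#'                       dut_bias = list(a = 0.9, b = 1, noise_sd = 0.05))
#' rep <- run_calibration_experiment(sc, seed = 42)
#' rep$before$mae; rep$after$mae
#' }
#' @export
run_calibration_experiment <- function(scenario, seed = NULL,
                                       fit_on = c("medians", "beats"),
                                       bp_range = c(100, 180)) {
  stopifnot(inherits(scenario, "scenario_config"))
  fit_on <- match.arg(fit_on)
  if (is.null(seed)) seed <- scenario$seed
  n_sp <- nrow(scenario$setpoints)
  stop_if(n_sp < 3, "at least 3 setpoints are needed to fit the MLR model")

  runs <- lapply(seq_len(n_sp), function(i) {
    run_setpoint(scenario, i, seed = derive_seed(seed, 100 + i))
  })
  summaries <- do.call(rbind, lapply(runs, `[[`, "summary"))
  summaries$true_pwv <- vapply(runs, `[[`, numeric(1), "true_pwv")
  summaries$pwv_theory <- mk_pwv(summaries$p_ref_mmhg, scenario$tube)

  if (fit_on == "medians") {
    p_fit <- summaries$p_ref_mmhg
    v_fit <- summaries$pwv_median
    t_fit <- summaries$pwv_theory
  } else {
    beats <- do.call(rbind, lapply(seq_along(runs), function(i) {
      m <- runs[[i]]$measurements
      m <- m[m$quality_flag == "ok", ]
      data.frame(p_ref = summaries$p_ref_mmhg[i], pwv = m$pwv_meas,
                 theory = summaries$pwv_theory[i])
    }))
    p_fit <- beats$p_ref; v_fit <- beats$pwv; t_fit <- beats$theory
  }
  model <- fit_mlr(p_fit, v_fit, t_fit)
  calibrated <- apply_calibration(model, summaries$p_ref_mmhg,
                                  summaries$pwv_median)
  summaries$pwv_calibrated <- calibrated

  agree <- function(est) {
    ba <- bland_altman(est, summaries$pwv_theory)
    m <- mae(est, summaries$pwv_theory)
    list(mae = m,
         mean_diff = ba$mean_diff, diff_sd = ba$diff_sd,
         loa_low = ba$loa_low, loa_high = ba$loa_high,
         bland_altman = ba,
         bp_error_band = bp_error_band(m, bp_range[1], bp_range[2],
                                       scenario$tube))
  }
  structure(
    list(summaries = summaries,
         model = model,
         before = agree(summaries$pwv_median),
         after = agree(calibrated),
         bp_range = bp_range,
         provenance = list(seed = as.integer(seed),
                           fit_on = fit_on,
                           scenario = scenario_to_list(scenario),
                           package_version =
                             as.character(utils::packageVersion("pwsim")))),
    class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Calibration experiment report\n")
  cat(sprintf("  setpoints: %d, fit on %s\n",
              nrow(x$summaries), x$provenance$fit_on))
  cat(sprintf("  MAE vs theory : %.4g m/s before, %.4g m/s after\n",
              x$before$mae, x$after$mae))
  cat(sprintf("  mean diff (sd): %.4g (%.4g) before, %.4g (%.4g) after\n",
              x$before$mean_diff, x$before$diff_sd,
              x$after$mean_diff, x$after$diff_sd))
  cat(sprintf(
    "  BP error band %g-%g mmHg: %.3g-%.3g mmHg before, %.3g-%.3g after\n",
    x$bp_range[1], x$bp_range[2],
    x$before$bp_error_band["at_p_high"], x$before$bp_error_band["at_p_low"],
    x$after$bp_error_band["at_p_high"], x$after$bp_error_band["at_p_low"]))
  invisible(x)
}

#' Calibrate an externally measured device
#'
#' The same fit and report for a real device: takes a table of per-setpoint
#' reference pressure and measured PWV (for example read from a CSV with
#' columns `setpoint_id`, `p_ref_mmhg`, `pwv_mps`), fits the MLR model
#' against the theoretical Moens-Korteweg PWV at each reference pressure and
#' reports before/after agreement.
#'
#' @param data Data frame with columns `p_ref_mmhg` and `pwv_mps` (one row
#'   per setpoint), or a path to such a CSV file.
#' @param tube A [tube_params()] describing the phantom.
#' @param bp_range Pressure range for the BP error bands, mmHg.
#' @return A list with `model`, `before`, `after` and the augmented `data`.
#' @export
calibrate_external <- function(data, tube = tube_params(),
                               bp_range = c(100, 180)) {
  if (is.character(data)) data <- read.csv(data)
  stop_if(!all(c("p_ref_mmhg", "pwv_mps") %in% names(data)),
          "'data' needs columns p_ref_mmhg and pwv_mps")
  theory <- mk_pwv(data$p_ref_mmhg, tube)
  model <- fit_mlr(data$p_ref_mmhg, data$pwv_mps, theory)
  calibrated <- apply_calibration(model, data$p_ref_mmhg, data$pwv_mps)
  data$pwv_theory <- theory
  data$pwv_calibrated <- calibrated
  agree <- function(est) {
    ba <- bland_altman(est, theory)
    m <- mae(est, theory)
    list(mae = m, mean_diff = ba$mean_diff, diff_sd = ba$diff_sd,
         loa_low = ba$loa_low, loa_high = ba$loa_high, bland_altman = ba,
         bp_error_band = bp_error_band(m, bp_range[1], bp_range[2], tube))
  }
  list(model = model, before = agree(data$pwv_mps),
       after = agree(calibrated), data = data)
}
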