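# Scenario configuration: the full parameter set for one bench experiment,
# with validated defaults and JSON/YAML round-tripping.

#' Scenario configuration
#'
#' Bundles every parameter of a calibration experiment: tube, pump,
#' reflection and acquisition parameters, the list of pressure setpoints,
#' the per-setpoint measurement duration, the device-under-test bias model
#' and the master seed.  Defaults describe the standard bench protocol:
#' nine setpoints spanning systolic pressures 100-180 mmHg over an 80 mmHg
#' base pressure, 60 s (75 beats at 75 bpm) per setpoint, 5 kHz sampling.
#'
#' The DUT bias model is an affine distortion with Gaussian per-beat noise,
#' `pwv_meas = a * pwv_true + b + N(0, noise_sd)` — the simplest family the
#' MLR calibration can correct exactly.
#'
#' @param tube A [tube_params()].
#' @param pump A [pump_params()].
#' @param refl A [reflection_params()].
#' @param acq An [acquisition_params()].
#' @param setpoints Data frame with columns `duty` and `base_pressure`.
#' @param duration_s Measurement duration per setpoint, s.
#' @param dut_bias List with `a`, `b` (m/s) and `noise_sd` (m/s).
#' @param seed Master seed; all random substreams derive from it.
#' @return An object of class `scenario_config`.
#' @examples
#' sc <- scenario_config(duration_s = 10)
#' @export
scenario_config <- function(tube = tube_params(),
                            pump = pump_params(),
                            refl = reflection_params(),
                            acq = acquisition_params(),
                            setpoints = default_setpoints(),
                            duration_s = 60,
                            dut_bias = list(a = 1, b = 0, noise_sd = 0),
                            seed = 1) {
  stopifnot(inherits(tube, "tube_params"), inherits(pump, "pump_params"),
            inherits(refl, "reflection_params"),
            inherits(acq, "acquisition_params"))
  stop_if(!is.data.frame(setpoints) ||
            !all(c("duty", "base_pressure") %in% names(setpoints)) ||
            nrow(setpoints) < 1,
          "'setpoints' must be a data frame with columns duty, base_pressure")
  check_scalar(duration_s, "duration_s")
  stop_if(!is.list(dut_bias) ||
            !all(c("a", "b", "noise_sd") %in% names(dut_bias)),
          "'dut_bias' must be a list with a, b, noise_sd")
  stop_if(dut_bias$noise_sd < 0, "'dut_bias$noise_sd' must be >= 0")
  check_scalar(seed, "seed", positive = FALSE)
  structure(
    list(tube = tube, pump = pump, refl = refl, acq = acq,
         setpoints = setpoints, duration_s = duration_s,
         dut_bias = dut_bias, seed = as.integer(seed)),
    class = "scenario_config")
}

#' @rdname scenario_config
#' @export
default_setpoints <- function() {
  data.frame(duty = seq(0.26, 0.90, by = 0.08), base_pressure = 80)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario: %d setpoints x %g s at %g bpm, fs %g Hz, seed %d\n",
    nrow(x$setpoints), x$duration_s, x$pump$heart_rate, x$acq$fs, x$seed))
  cat(sprintf("  DUT bias: pwv_meas = %g * pwv + %g + N(0, %g)\n",
              x$dut_bias$a, x$dut_bias$b, x$dut_bias$noise_sd))
  invisible(x)
}

# Internal: deterministic substream seed derived from the master seed.
# Keeps results reproducible per component while independent across them.
derive_seed <- function(master, k) {
  s <- (as.numeric(master) %% 2147483647) * 69069 + as.numeric(k) * 1000003
  as.integer(s %% 2147483629) + 1L
}

#' Convert a scenario to/from plain lists (for JSON/YAML files)
#'
#' `scenario_to_list()` produces a nested plain list; [load_scenario()]
#' reads a JSON or YAML file, fills unset fields with the defaults and
#' validates everything, erroring on unknown keys.
#'
#' @param scenario A [scenario_config()].
#' @return A nested plain list.
#' @export
scenario_to_list <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  list(tube = unclass(scenario$tube),
       pump = unclass(scenario$pump),
       reflection = drop_null(unclass(scenario$refl)),
       acquisition = drop_null(unclass(scenario$acq)),
       setpoints = as.list(scenario$setpoints),
       duration_s = scenario$duration_s,
       dut_bias = scenario$dut_bias,
       seed = scenario$seed)
}

#' Load and validate a scenario configuration file
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.  Fields not
#'   present take the documented defaults; unknown fields are an error.
#' @return A validated [scenario_config()].
#' @export
load_scenario <- function(path) {
  stop_if(!file.exists(path), sprintf("config file '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml", call. = FALSE))
  if (is.null(raw)) raw <- list()
  scenario_from_list(raw)
}

#' @rdname load_scenario
#' @param x Nested plain list as produced by [scenario_to_list()].
#' @export
scenario_from_list <- function(x) {
  known <- c("tube", "pump", "reflection", "acquisition", "setpoints",
             "duration_s", "dut_bias", "seed")
  extra <- setdiff(names(x), known)
  stop_if(length(extra) > 0,
          "unknown config field(s): ", paste(extra, collapse = ", "))
  build <- function(ctor, part, name) {
    part <- as.list(part)
    bad <- setdiff(names(part), names(formals(ctor)))
    stop_if(length(bad) > 0,
            sprintf("unknown field(s) in '%s': %s", name,
                    paste(bad, collapse = ", ")))
    # NULL reflection_delay round-trips as absent; drop NULL/empty values
    keep <- !vapply(part, function(v) is.null(v) || length(v) == 0, logical(1))
    do.call(ctor, part[keep])
  }
  tube <- build(tube_params, x$tube, "tube")
  pump <- build(pump_params, x$pump, "pump")
  refl <- build(reflection_params, x$reflection, "reflection")
  acq <- build(acquisition_params, x$acquisition, "acquisition")
  setpoints <- if (is.null(x$setpoints)) default_setpoints() else
    as.data.frame(x$setpoints)
  args <- list(tube = tube, pump = pump, refl = refl, acq = acq,
               setpoints = setpoints)
  if (!is.null(x$duration_s)) args$duration_s <- x$duration_s
  if (!is.null(x$dut_bias)) args$dut_bias <- as.list(x$dut_bias)
  if (!is.null(x$seed)) args$seed <- x$seed
  do.call(scenario_config, args)
}
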