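#' Uniformly sampled pressure series
#'
#' A pressure (or post-filter sensor-voltage) trace sampled on a uniform
#' grid.  This is the common currency between the simulator, the acquisition
#' chain and the estimator.
#'
#' @param samples Numeric vector of sample values (mmHg for raw pressure,
#'   arbitrary pressure-equivalent units after filtering).
#' @param fs Sampling rate, Hz.
#' @param t0 Time of the first sample, s.
#' @param label Channel label.
#' @return An object of class `pressure_series`.
#' @examples
#' s <- pressure_series(sin(2 * pi * 1.25 * (0:999) / 250), fs = 250)
#' series_duration(s)
#' @export
pressure_series <- function(samples, fs, t0 = 0, label = "pressure") {
  stop_if(!is.numeric(samples) || length(samples) == 0L,
          "'samples' must be a non-empty numeric vector")
  stop_if(any(!is.finite(samples)), "'samples' must be finite")
  check_scalar(fs, "fs")
  check_scalar(t0, "t0", positive = FALSE)
  structure(
    list(samples = as.numeric(samples), fs = fs, t0 = t0,
         label = as.character(label)[1]),
    class = "pressure_series")
}

#' @rdname pressure_series
#' @param x A `pressure_series`.
#' @export
series_time <- function(x) {
  stopifnot(inherits(x, "pressure_series"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

#' @rdname pressure_series
#' @export
series_duration <- function(x) {
  stopifnot(inherits(x, "pressure_series"))
  length(x$samples) / x$fs
}

#' @export
length.pressure_series <- function(x) length(x$samples)

#' @export
as.data.frame.pressure_series <- function(x, ...) {
  data.frame(time_s = series_time(x), value = x$samples)
}

#' @export
print.pressure_series <- function(x, ...) {
  cat(sprintf("Pressure series '%s': %d samples at %g Hz (%.3g s)\n",
              x$label, length(x$samples), x$fs, series_duration(x)))
  cat(sprintf("  range [%.4g, %.4g], t0 = %g s\n",
              min(x$samples), max(x$samples), x$t0))
  invisible(x)
}

# Internal: copy a series with new samples, keeping grid metadata.
series_with <- function(x, samples, label = x$label) {
  pressure_series(samples, fs = x$fs, t0 = x$t0, label = label)
}
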