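# File interfaces: trace and record CSVs with JSON sidecars carrying
# provenance, beat/summary tables, and the report JSON.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read a pressure trace as CSV with a JSON sidecar
#'
#' The CSV has columns `time_s` and `pressure_mmHg`; the sidecar JSON next
#' to it carries the sampling rate, time origin, label and any provenance
#' (setpoint, seed, parameters) so the trace is self-describing.
#'
#' @param series A [pressure_series()].
#' @param path Output CSV path.
#' @param provenance Named list written into the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(series, path, provenance = list()) {
  stopifnot(inherits(series, "pressure_series"))
  df <- data.frame(time_s = series_time(series),
                   pressure_mmHg = series$samples)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- c(list(fs = series$fs, t0 = series$t0, label = series$label),
            provenance)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @return `read_trace_csv()`: a [pressure_series()] with the sidecar
#'   metadata attached as attribute `"provenance"`.
#' @export
read_trace_csv <- function(path) {
  stop_if(!file.exists(path), sprintf("trace file '%s' does not exist", path))
  df <- read.csv(path)
  stop_if(nrow(df) == 0, sprintf("trace file '%s' is empty", path))
  stop_if(!all(c("time_s", "pressure_mmHg") %in% names(df)),
          sprintf("'%s' must have columns time_s, pressure_mmHg", path))
  side <- sidecar_path(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
    else list()
  fs <- if (!is.null(meta$fs)) meta$fs else {
    stop_if(nrow(df) < 2, "cannot infer sampling rate from one sample")
    1 / mean(diff(df$time_s))
  }
  s <- pressure_series(df$pressure_mmHg, fs = fs,
                       t0 = if (!is.null(meta$t0)) meta$t0 else df$time_s[1],
                       label = if (!is.null(meta$label)) meta$label else "pressure")
  attr(s, "provenance") <- meta
  s
}

#' Write / read a two-channel record as CSV with a JSON sidecar
#'
#' Three columns (`time_s`, `proximal`, `distal`); the sidecar carries the
#' ground-truth delay and full parameter provenance.
#'
#' @param record A [two_channel_record()].
#' @param path Output CSV path.
#' @return `path` (write) or a [two_channel_record()] (read), invisibly.
#' @export
write_record_csv <- function(record, path) {
  stopifnot(inherits(record, "two_channel_record"))
  df <- data.frame(time_s = series_time(record$proximal),
                   proximal = record$proximal$samples,
                   distal = record$distal$samples)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(fs = record$proximal$fs, t0 = record$proximal$t0,
               true_delay_s = record$true_delay, meta = record$meta)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_record_csv
#' @export
read_record_csv <- function(path) {
  stop_if(!file.exists(path), sprintf("record file '%s' does not exist", path))
  df <- read.csv(path)
  stop_if(nrow(df) == 0, sprintf("record file '%s' is empty", path))
  side <- sidecar_path(path)
  stop_if(!file.exists(side),
          sprintf("sidecar '%s' is required to read a record", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  prox <- pressure_series(df$proximal, fs = meta$fs, t0 = meta$t0,
                          label = "proximal")
  dist <- pressure_series(df$distal, fs = meta$fs, t0 = meta$t0,
                          label = "distal")
  two_channel_record(prox, dist, true_delay = meta$true_delay_s,
                     meta = if (is.null(meta$meta)) list() else meta$meta)
}

#' Write a calibration report as pretty-printed JSON
#'
#' Statistics, per-setpoint table, model coefficients and provenance are
#' written as a single JSON document (stable field order, full precision)
#' so that identical configuration and seed give byte-identical files.
#'
#' @param report A [run_calibration_experiment()] report.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "calibration_report"))
  strip <- function(a) {
    list(mae = a$mae, mean_diff = a$mean_diff, diff_sd = a$diff_sd,
         loa_low = a$loa_low, loa_high = a$loa_high,
         bp_error_band = as.list(a$bp_error_band))
  }
  out <- list(
    summaries = report$summaries,
    model = list(beta0 = report$model$beta0, beta1 = report$model$beta1,
                 beta2 = report$model$beta2, n_fit = report$model$n_fit,
                 residual_sd = report$model$residual_sd),
    before = strip(report$before),
    after = strip(report$after),
    bp_range_mmhg = report$bp_range,
    provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
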