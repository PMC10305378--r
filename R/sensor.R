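# The DUT acquisition path: inter-sensor propagation delay, zero-phase
# band-pass filtering (analog front end then digital FIR), sampling noise.

# Internal: delay x by a (possibly fractional) number of samples.
# Integer part by index shift; fractional part by windowed-sinc (Hann)
# band-limited interpolation.  'pad' fills the leading edge (NA = edge value).
frac_delay_shift <- function(x, delay_samples, pad = NA, half_width = 40L) {
  n <- length(x)
  d0 <- floor(delay_samples)
  f <- delay_samples - d0
  pad_head <- if (is.na(pad)) x[1] else pad
  pad_tail <- if (is.na(pad)) x[n] else pad
  if (f < 1e-12) {
    y <- x
  } else {
    k <- seq.int(-half_width, half_width)
    h <- sinc(k - f) * hann_frac(k - f, half_width + 1)
    h <- h / sum(h)
    xp <- c(rep(pad_head, half_width), x, rep(pad_tail, half_width))
    y <- numeric(n)
    # y[i] = sum_k h[k] * x[i - k]  (delay by f)
    for (j in seq_along(k)) {
      y <- y + h[j] * xp[seq_len(n) + half_width - k[j]]
    }
  }
  if (d0 > 0) {
    y <- c(rep(pad_head, d0), y[seq_len(n - d0)])
  } else if (d0 < 0) {
    y <- c(y[(1 - d0):n], rep(pad_tail, -d0))
  }
  y
}

sinc <- function(t) ifelse(abs(t) < 1e-12, 1, sin(pi * t) / (pi * t))

hann_frac <- function(t, half) {
  w <- 0.5 * (1 + cos(pi * t / half))
  w[abs(t) >= half] <- 0
  w
}

#' Two-channel sensor record
#'
#' The proximal and distal channels seen by the DUT's two sensors, with the
#' ground-truth inter-sensor delay retained for evaluation.
#'
#' @param proximal,distal [pressure_series()] objects on the same grid.
#' @param true_delay Ground-truth inter-channel delay, s.
#' @param meta Optional list of provenance (setpoint, parameters).
#' @return An object of class `two_channel_record`.
#' @export
two_channel_record <- function(proximal, distal, true_delay, meta = list()) {
  stopifnot(inherits(proximal, "pressure_series"),
            inherits(distal, "pressure_series"))
  stop_if(proximal$fs != distal$fs ||
            length(proximal$samples) != length(distal$samples),
          "channels must share sampling rate and length")
  check_scalar(true_delay, "true_delay", positive = FALSE)
  stop_if(true_delay < 0, "'true_delay' must be >= 0")
  structure(list(proximal = proximal, distal = distal,
                 true_delay = true_delay, meta = meta),
            class = "two_channel_record")
}

#' @export
print.two_channel_record <- function(x, ...) {
  cat(sprintf(
    "Two-channel record: %d samples at %g Hz, true delay %.4g ms\n",
    length(x$proximal$samples), x$proximal$fs, s_to_ms(x$true_delay)))
  invisible(x)
}

#' Propagate a pressure trace past two sensors
#'
#' The distal channel is the proximal trace delayed by the transit time
#' `L / pwv` over the sensor spacing L, using band-limited fractional-sample
#' interpolation.  The ground-truth delay is recorded in the output.
#'
#' @param beat_series A [pressure_series()] at the proximal site.
#' @param pwv Wave speed in the phantom, m/s.
#' @param L Sensor spacing, cm.
#' @param meta Optional provenance list carried into the record.
#' @return A [two_channel_record()] (pre-filter).
#' @examples
#' s <- synth_pressure_series(duty_to_setpoint(0.4, 80), duration = 2, fs = 1000)
#' rec <- propagate(s, pwv = 2, L = 4)
#' s_to_ms(rec$true_delay)   # 20 ms
#' @export
propagate <- function(beat_series, pwv, L = 4, meta = list()) {
  stopifnot(inherits(beat_series, "pressure_series"))
  check_scalar(pwv, "pwv")
  check_scalar(L, "L")
  delay <- cm_to_m(L) / pwv
  stop_if(delay >= series_duration(beat_series),
          "transit delay is not shorter than the trace")
  dist <- series_with(beat_series,
                      frac_delay_shift(beat_series$samples,
                                       delay * beat_series$fs),
                      label = "distal")
  prox <- series_with(beat_series, beat_series$samples, label = "proximal")
  two_channel_record(prox, dist, true_delay = delay, meta = meta)
}

# Internal: exact zero-phase response of a linear-phase FIR, applied
# circularly in the frequency domain.  For traces shorter than the filter
# the FIR is redesigned at the largest odd length that fits.
fir_zero_phase <- function(x, fs, band, fir_taps) {
  n <- length(x)
  taps <- min(as.integer(fir_taps), if (n %% 2L == 1L) n else n - 1L)
  if (taps %% 2L == 0L) taps <- taps - 1L
  stop_if(taps < 3L, "series too short to filter")
  h <- signal::fir1(taps - 1L, band / (fs / 2), type = "pass")
  m <- (taps - 1L) %/% 2L
  hh <- numeric(n)
  hh[1] <- h[m + 1]
  hh[2:(m + 1)] <- h[(m + 2):taps]
  hh[(n - m + 1):n] <- h[1:m]
  H <- Re(fft(hh))
  Re(fft(fft(x) * H, inverse = TRUE)) / n
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR applied with exactly zero phase,
#' so that an identical filter on the two channels preserves their relative
#' delay.  The DC component is rejected by the high-pass edge.  Filtering is
#' circular (periodic extension), the natural boundary treatment for the
#' simulator's periodic beat trains.
#'
#' @param series A [pressure_series()].
#' @param band Band edges c(low, high), Hz; must satisfy
#'   `0 < low < high < fs/2`.
#' @param fir_taps Filter length (odd); reduced automatically for short
#'   traces.  See [acquisition_params()] for the default rationale.
#' @return A filtered [pressure_series()] (zero-mean pulsatile units).
#' @examples
#' s <- pressure_series(100 + sin(2 * pi * 1.25 * (0:4999) / 500), fs = 500)
#' f <- bandpass(s, c(0.7, 9.5))
#' @export
bandpass <- function(series, band, fir_taps = 16385) {
  stopifnot(inherits(series, "pressure_series"))
  stop_if(!is.numeric(band) || length(band) != 2L ||
            band[1] <= 0 || band[2] <= band[1],
          "'band' must be c(low, high) with 0 < low < high")
  stop_if(band[2] >= series$fs / 2, "'band' upper edge must be below Nyquist")
  series_with(series,
              fir_zero_phase(series$samples, series$fs, band, fir_taps),
              label = paste0(series$label, "_bp"))
}

#' Run a two-channel record through the DUT acquisition chain
#'
#' Both channels pass the analog front-end band-pass, receive independent
#' additive white Gaussian noise at the sampling stage (where sensor and ADC
#' noise enters the real device), and then pass the digital FIR band-pass.
#' The two noise streams are drawn from one seeded generator, so a fixed
#' seed reproduces the record bit for bit.
#'
#' @param record A [two_channel_record()] (raw pressure).
#' @param params An [acquisition_params()] object.
#' @return A filtered, noisy [two_channel_record()]; `true_delay` and `meta`
#'   are carried through.
#' @export
acquire <- function(record, params = acquisition_params()) {
  stopifnot(inherits(record, "two_channel_record"),
            inherits(params, "acquisition_params"))
  stop_if(record$proximal$fs != params$fs,
          "record sampling rate does not match acquisition 'fs'")
  prox <- bandpass(record$proximal, params$analog_band, params$fir_taps)
  dist <- bandpass(record$distal, params$analog_band, params$fir_taps)
  if (params$noise_sd > 0) {
    if (!is.null(params$seed)) set.seed(params$seed)
    n <- length(prox$samples)
    prox <- series_with(prox, prox$samples + rnorm(n, 0, params$noise_sd))
    dist <- series_with(dist, dist$samples + rnorm(n, 0, params$noise_sd))
  }
  prox <- bandpass(prox, params$digital_band, params$fir_taps)
  dist <- bandpass(dist, params$digital_band, params$fir_taps)
  two_channel_record(prox, dist, true_delay = record$true_delay,
                     meta = c(record$meta, list(acquisition = unclass(params))))
}
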