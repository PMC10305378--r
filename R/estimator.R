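# The DUT's measurement algorithm: first-peak detection on each channel,
# peak pairing across channels, per-beat PTT/PWV, per-setpoint summaries.

#' Detect the first (highest-gradient) peak of each beat
#'
#' Implements the DUT's discriminator: a peak is accepted only when the
#' upstroke leading into it is steep.  Candidate upstrokes are rising
#' crossings of the smoothed derivative over an adaptive threshold
#' (`grad_frac` of the trace's maximum upstroke gradient); a refractory
#' period of 60% of the expected beat keeps at most one detection per beat.
#' The reflected wave's secondary peak has a smaller gradient than the
#' primary upstroke (its amplitude ratio is below 1), so it never crosses
#' the gate.  The returned time of each peak is the first local maximum
#' after the gradient crossing, optionally refined to sub-sample precision
#' by a least-squares parabola over the peak neighbourhood (robust to
#' in-band noise; any residual shape bias is common to both channels and
#' cancels in the transit time).
#'
#' @param series A filtered, zero-mean pulsatile [pressure_series()].
#' @param hr_hint Expected heart rate, beats/min (sets the refractory
#'   period).
#' @param grad_frac Gradient gate as a fraction of the maximum upstroke
#'   gradient.
#' @param smooth_ms Moving-average width used to stabilise the derivative
#'   against sample noise, ms.
#' @param refine Logical; parabolic sub-sample refinement of peak times.
#'   Turn off to evaluate the raw one-sample (0.2 ms at 5 kHz) timing
#'   resolution.
#' @return Numeric vector of peak times, s (possibly empty).
#' @export
detect_first_peaks <- function(series, hr_hint = 75, grad_frac = 0.5,
                               smooth_ms = 15, refine = TRUE) {
  stopifnot(inherits(series, "pressure_series"))
  check_scalar(hr_hint, "hr_hint")
  x <- series$samples
  fs <- series$fs
  n <- length(x)
  if (n < 5 || max(x) - min(x) < 1e-12) return(numeric(0))

  w <- max(1L, round(smooth_ms / 1000 * fs))
  if (w %% 2L == 0L) w <- w + 1L
  xs <- if (w > 1L) {
    as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  } else x
  # moving average leaves NA at the edges; hold the edge values
  if (w > 1L) {
    half <- (w - 1L) %/% 2L
    xs[seq_len(half)] <- xs[half + 1L]
    xs[(n - half + 1L):n] <- xs[n - half]
  }
  g <- c(0, diff(xs)) * fs
  gmax <- max(g)
  if (gmax <= 0) return(numeric(0))
  thr <- grad_frac * gmax

  period <- fs * 60 / hr_hint
  refractory <- round(0.6 * period)
  cross <- which(g[-1] >= thr & g[-n] < thr) + 1L
  if (length(cross) == 0) return(numeric(0))
  keep <- cross[1]
  for (i in cross[-1]) {
    if (i - keep[length(keep)] >= refractory) keep <- c(keep, i)
  }

  peaks <- vapply(keep, function(i) {
    jmax <- min(n - 1L, i + round(period))
    j <- i
    while (j < jmax && xs[j + 1L] >= xs[j]) j <- j + 1L
    if (j >= jmax || j <= 1L) return(NA_real_)   # ran off the trace edge
    if (refine) {
      # quadratic least squares over +-6% of the beat period around the max
      hw <- max(2L, round(0.06 * period))
      lo <- max(1L, j - hw); hi <- min(n, j + hw)
      k <- (lo:hi) - j
      fit <- stats::lm.fit(cbind(1, k, k * k), xs[lo:hi])
      a <- fit$coefficients[3]; b <- fit$coefficients[2]
      delta <- if (is.finite(a) && a < 0) -b / (2 * a) else 0
      delta <- max(-hw, min(hw, delta))
      (j - 1 + delta) / fs
    } else {
      (j - 1) / fs
    }
  }, numeric(1))
  series$t0 + peaks[!is.na(peaks)]
}

#' Pair proximal/distal peaks and compute per-beat transit times
#'
#' Each proximal peak is paired with the nearest subsequent distal peak
#' within `max_ptt`; each distal peak is used at most once.  Unpaired beats
#' are kept with flag `"rejected"`.  The per-beat PTT is quantized at one
#' sample period (0.2 ms at 5 kHz) unless sub-sample peak refinement was
#' used upstream; PWV follows as `L / PTT`.
#'
#' @param prox_peaks,dist_peaks Time-sorted peak times, s.
#' @param max_ptt Largest plausible transit time, ms.
#' @param L Sensor spacing, cm.
#' @return A data frame of beat measurements with columns `beat_index`,
#'   `peak_time_proximal`, `peak_time_distal`, `ptt_ms`, `pwv_mps`,
#'   `quality_flag`.
#' @examples
#' pair_and_ptt(c(0.1, 0.9), c(0.11, 0.91))
#' @export
pair_and_ptt <- function(prox_peaks, dist_peaks, max_ptt = 60, L = 4) {
  check_scalar(max_ptt, "max_ptt")
  stop_if(is.unsorted(prox_peaks) || is.unsorted(dist_peaks),
          "peak sequences must be time-sorted")
  n <- length(prox_peaks)
  out <- data.frame(beat_index = seq_len(n),
                    peak_time_proximal = as.numeric(prox_peaks),
                    peak_time_distal = NA_real_,
                    ptt_ms = NA_real_,
                    pwv_mps = NA_real_,
                    quality_flag = rep("rejected", n),
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  used <- rep(FALSE, length(dist_peaks))
  for (i in seq_len(n)) {
    cand <- which(!used & dist_peaks > prox_peaks[i] &
                    dist_peaks <= prox_peaks[i] + max_ptt / 1000)
    if (length(cand) == 0) next
    j <- cand[which.min(dist_peaks[cand] - prox_peaks[i])]
    used[j] <- TRUE
    ptt <- s_to_ms(dist_peaks[j] - prox_peaks[i])
    out$peak_time_distal[i] <- dist_peaks[j]
    out$ptt_ms[i] <- ptt
    out$pwv_mps[i] <- pwv_from_ptt(ptt, L)
    out$quality_flag[i] <- "ok"
  }
  out
}

#' Summarize the beats measured at one setpoint
#'
#' Median, mean and standard deviation of the accepted beats' PWV, together
#' with the setpoint's reference pressure: the mean of the windowed RMS of
#' the simulator's pressure-sensor trace (see [rms_reference_map()]).
#'
#' @param measurements Beat measurements from [pair_and_ptt()].
#' @param p_ref_series Raw pressure trace of the simulator's sensor, mmHg.
#' @param window_s RMS window, s.
#' @param setpoint_id Identifier carried into the summary row.
#' @return One-row data frame with columns `setpoint_id`, `n_beats`,
#'   `pwv_median`, `pwv_mean`, `pwv_sd`, `p_ref_mmhg`.
#' @export
summarize_setpoint <- function(measurements, p_ref_series, window_s = 1,
                               setpoint_id = NA) {
  stopifnot(is.data.frame(measurements))
  ok <- measurements[measurements$quality_flag == "ok", , drop = FALSE]
  stop_if(nrow(ok) == 0, "no accepted beats at this setpoint")
  pwv <- ok$pwv_mps
  p_ref <- mean(rms_reference_map(p_ref_series, window_s))
  data.frame(setpoint_id = setpoint_id,
             n_beats = nrow(ok),
             pwv_median = median(pwv),
             pwv_mean = mean(pwv),
             pwv_sd = if (nrow(ok) > 1) sd(pwv) else 0,
             p_ref_mmhg = p_ref,
             stringsAsFactors = FALSE)
}

#' Measure a two-channel record with the DUT algorithm
#'
#' Convenience wrapper: detect first peaks on both channels, pair them and
#' compute per-beat PTT/PWV.
#'
#' @param record An acquired [two_channel_record()].
#' @param hr_hint Expected heart rate, beats/min.
#' @param L Sensor spacing, cm.
#' @param max_ptt Largest plausible transit time, ms.
#' @param refine Sub-sample peak refinement (see [detect_first_peaks()]).
#' @return A beat-measurement data frame (see [pair_and_ptt()]).
#' @export
measure_record <- function(record, hr_hint = 75, L = 4, max_ptt = 60,
                           refine = TRUE) {
  stopifnot(inherits(record, "two_channel_record"))
  prox <- detect_first_peaks(record$proximal, hr_hint, refine = refine)
  dist <- detect_first_peaks(record$distal, hr_hint, refine = refine)
  pair_and_ptt(prox, dist, max_ptt = max_ptt, L = L)
}
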