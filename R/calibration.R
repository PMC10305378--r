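# MLR calibration of measured PWV onto the Moens-Korteweg theoretical curve,
# and the agreement statistics used to evaluate it.

#' Fit the multiple linear regression calibration model
#'
#' Ordinary least squares for `c = beta0 + beta1 * P_ref + beta2 * PWV_ref`,
#' where `P_ref` is the simulator's reference pressure (mmHg), `PWV_ref` the
#' device's measured PWV (m/s) and the target the theoretical
#' Moens-Korteweg PWV.  The fitted map calibrates the device onto the
#' theoretical curve.
#'
#' @param p_ref Reference pressures, mmHg.
#' @param pwv_ref Measured (reference-device) PWV values, m/s.
#' @param target Calibration targets, m/s (theoretical PWV).
#' @return An object of class `calibration_model`: a list with `beta0`,
#'   `beta1`, `beta2`, `n_fit`, `residual_sd` and the underlying `lm` fit.
#' @examples
#' p <- c(90, 100, 110, 120); v <- c(2.5, 2.8, 3.1, 3.4)
#' m <- fit_mlr(p, v, 0.5 + 0.01 * p + 0.9 * v)
#' coef(m$fit)
#' @export
fit_mlr <- function(p_ref, pwv_ref, target) {
  stop_if(length(p_ref) != length(pwv_ref) || length(p_ref) != length(target),
          "'p_ref', 'pwv_ref' and 'target' must have equal length")
  stop_if(length(p_ref) < 3,
          "at least 3 observations are needed for 3 coefficients")
  stop_if(sd(p_ref) < 1e-12, "design is rank deficient: 'p_ref' is constant")
  stop_if(sd(pwv_ref) < 1e-12, "design is rank deficient: 'pwv_ref' is constant")
  dat <- data.frame(target = target, p_ref = p_ref, pwv_ref = pwv_ref)
  fit <- lm(target ~ p_ref + pwv_ref, data = dat)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("design is rank deficient: collinear column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- unname(coef(fit))
  structure(
    list(beta0 = beta[1], beta1 = beta[2], beta2 = beta[3],
         n_fit = length(target),
         residual_sd = sqrt(sum(fit$residuals^2) /
                              max(1, fit$df.residual)),
         fit = fit),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("PWV calibration model: c = beta0 + beta1 * P_ref + beta2 * PWV_ref\n")
  cat(sprintf("  beta0 = %.6g m/s\n", x$beta0))
  cat(sprintf("  beta1 = %.6g m/s per mmHg\n", x$beta1))
  cat(sprintf("  beta2 = %.6g\n", x$beta2))
  cat(sprintf("  n = %d, residual sd = %.4g m/s\n", x$n_fit, x$residual_sd))
  invisible(x)
}

#' Apply a fitted calibration model
#'
#' @param model A [fit_mlr()] model.
#' @param p_ref Reference pressures, mmHg.
#' @param pwv_meas Measured PWV values, m/s.
#' @return Calibrated PWV, m/s.
#' @export
apply_calibration <- function(model, p_ref, pwv_meas) {
  stopifnot(inherits(model, "calibration_model"))
  model$beta0 + model$beta1 * p_ref + model$beta2 * pwv_meas
}

#' Mean absolute error
#'
#' @param x,y Paired numeric vectors of equal, nonzero length.
#' @return `mean(abs(x - y))`.
#' @examples
#' mae(c(1, 2), c(2, 4))   # 1.5
#' @export
mae <- function(x, y) {
  stop_if(length(x) != length(y), "'x' and 'y' must have equal length")
  stop_if(length(x) == 0, "empty input")
  mean(abs(x - y))
}

#' Bland-Altman agreement analysis
#'
#' Mean difference, sample standard deviation of the differences (n-1
#' denominator) and the 1.96-sd limits of agreement for paired measurements,
#' plus the per-pair (mean, difference) table used for plotting.
#'
#' @param a,b Paired numeric vectors (differences are `a - b`), length >= 2.
#' @return A list of class `bland_altman` with `mean_diff`, `diff_sd`,
#'   `loa_low`, `loa_high`, `n` and a data frame `table` with columns
#'   `mean` and `diff`.
#' @examples
#' ba <- bland_altman(c(3, 4, 5), c(2.9, 4.2, 4.8))
#' ba$mean_diff
#' @export
bland_altman <- function(a, b) {
  stop_if(length(a) != length(b), "'a' and 'b' must have equal length")
  stop_if(length(a) < 2, "at least 2 pairs are required")
  d <- a - b
  md <- mean(d)
  s <- sd(d)
  structure(
    list(mean_diff = md, diff_sd = s,
         loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
         n = length(d),
         table = data.frame(mean = (a + b) / 2, diff = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean diff %.4g, sd %.4g, LoA [%.4g, %.4g]\n",
    x$n, x$mean_diff, x$diff_sd, x$loa_low, x$loa_high))
  invisible(x)
}

#' Blood-pressure error band for a PWV deviation
#'
#' Evaluates [bp_error_from_pwv_error()] at the Moens-Korteweg operating
#' PWV of the two ends of a pressure range and returns the magnitude at
#' each end.  The band is wider at the lower pressure because the PWV curve
#' is flatter there: a fixed PWV deviation maps to a larger pressure error
#' when the wave is slower.
#'
#' @param dpwv PWV deviation, m/s.
#' @param p_low,p_high Ends of the evaluated pressure range, mmHg.
#' @param tube A [tube_params()] object.
#' @return Named numeric vector `c(at_p_low = ..., at_p_high = ...)`, mmHg
#'   (magnitudes).
#' @examples
#' bp_error_band(0.77, 100, 180)
#' @export
bp_error_band <- function(dpwv, p_low = 100, p_high = 180,
                          tube = tube_params()) {
  stop_if(p_low >= p_high, "'p_low' must be below 'p_high'")
  stop_if(!is.finite(dpwv), "'dpwv' must be finite")
  v <- mk_pwv(c(p_low, p_high), tube)
  err <- abs(bp_error_from_pwv_error(v, dpwv, tube))
  setNames(err, c("at_p_low", "at_p_high"))
}
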