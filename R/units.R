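# Unit conversion layer: SI internally (m, s, Pa, kg/m^3), conventional
# clinical units (mmHg, cm, ms) at the interfaces.

MMHG_PA <- 133.322

mmhg_to_pa <- function(p) p * MMHG_PA
pa_to_mmhg <- function(p) p / MMHG_PA
mm_to_m <- function(x) x / 1000
cm_to_m <- function(x) x / 100
ms_to_s <- function(x) x / 1000
s_to_ms <- function(x) x * 1000

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

check_scalar <- function(x, name, positive = TRUE, finite = TRUE) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x),
          sprintf("'%s' must be a single non-missing number", name))
  if (finite) stop_if(!is.finite(x), sprintf("'%s' must be finite", name))
  if (positive) stop_if(x <= 0, sprintf("'%s' must be strictly positive", name))
  invisible(x)
}
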