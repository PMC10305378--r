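# Shared fixtures: small, fast configurations used across test files.
# Whole-beat durations are used throughout (the bench protocol measures an
# integer number of beats per window; see the methods vignette).

default_tube <- tube_params()

# A light scenario for end-to-end tests: 8 s windows (10 beats at 75 bpm)
# at 1 kHz keep each experiment under a second.
fast_scenario <- function(...) {
  args <- list(acq = acquisition_params(fs = 1000), duration_s = 8)
  user <- list(...)
  args[names(user)] <- user
  do.call(scenario_config, args)
}

# One clean acquired record at 5 kHz, memoised because several tests reuse it.
local({
  cache <- new.env(parent = emptyenv())
  clean_record_5k <<- function(pwv = 3, noise_sd = 0, seed = 9) {
    key <- paste(pwv, noise_sd, seed)
    if (is.null(cache[[key]])) {
      sp <- duty_to_setpoint(0.42, 80)
      s <- synth_pressure_series(sp, pump_params(), reflection_params(),
                                 duration = 4, fs = 5000, seed = 1)
      rec <- propagate(s, pwv, L = 4)
      cache[[key]] <- acquire(rec, acquisition_params(noise_sd = noise_sd,
                                                      seed = seed))
    }
    cache[[key]]
  }
})

# Independent brute-force cross-correlation lag (integer samples): the lag
# of b after a maximising the circular correlation.  Wrap-around avoids the
# truncation bias of a finite window on these periodic beat trains.
xcorr_lag <- function(a, b, max_lag) {
  a <- a - mean(a); b <- b - mean(b)
  n <- length(a)
  cors <- vapply(0:max_lag, function(k) {
    idx <- ((seq_len(n) - 1 + k) %% n) + 1
    sum(a * b[idx])
  }, numeric(1))
  (0:max_lag)[which.max(cors)]
}
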