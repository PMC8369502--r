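# Shared fixtures. Calibrated beat shapes are cached across tests (they are
# deterministic for a given preset and measurement grid).

.shape_cache <- new.env(parent = emptyenv())

cached_shape <- function(preset, sampling_interval = 5) {
  key <- paste(preset$name, preset$beat_rate, preset$noise_sd,
               paste(round(preset$capd_targets, 3), collapse = ","),
               sampling_interval, sep = "|")
  if (is.null(.shape_cache[[key]])) {
    .shape_cache[[key]] <- calibrate_preset(preset, sampling_interval)
  }
  .shape_cache[[key]]
}

# noise-free variant of a default preset
clean_preset <- function(group) {
  p <- default_preset(group)
  p$noise_sd <- 0
  p$drift_rate <- 0
  p$rate_jitter_cv <- 0
  p
}

gen <- function(preset, duration = 30, sampling_interval = 5, seed = 1, ...) {
  generate_trace(preset, duration = duration,
                 sampling_interval = sampling_interval, seed = seed,
                 shape = cached_shape(preset, min(sampling_interval, 5)), ...)
}

# step-up, linear-decay beat with exact analytic durations:
# activation/peak at t0, amplitude A, back to baseline at t0 + decay_s
triangle_trace <- function(t0 = 0.3, A = 1, decay_s = 0.1, dt = 0.005,
                           duration = 1) {
  t <- seq(0, duration, by = dt)
  sig <- ifelse(t >= t0 & t <= t0 + decay_s, A * (1 - (t - t0) / decay_s), 0)
  new_trace("T1", t, sig, dt * 1000)
}
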