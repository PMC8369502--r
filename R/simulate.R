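# Counter-based seeding: each well seed spawns independent sub-streams so that
# injecting an event never perturbs the draws of another component (beat
# onsets, measurement noise, event bookkeeping stay on separate streams).
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream) %% 2147483647L)
}

STREAM_IBI <- 1L
STREAM_NOISE <- 2L
STREAM_EVENT <- 3L

draw_stream <- function(seed, stream, n, what = c("norm", "unif")) {
  what <- match.arg(what)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  if (what == "norm") stats::rnorm(n) else stats::runif(n)
}

#' Generate a synthetic optical trace for one well
#'
#' Renders a fluorescence time series with the structure the analysis pipeline
#' assumes: calibrated subtype-specific beats at jittered onsets on a
#' diastolic baseline, multiplicative photobleaching drift, and i.i.d.
#' Gaussian measurement noise. Optionally injects an arrhythmia-like event
#' (see [inject_event()]). All randomness derives from `seed` through
#' independent sub-streams, so identical `(preset, seed)` calls are
#' bitwise-identical and event injection does not perturb the onset or noise
#' draws.
#'
#' The first beat is activated 0.15 s into the recording; only beats whose
#' full waveform support fits inside the recording are realized, and every
#' realized onset is recorded in the ground truth attached to the trace.
#'
#' @param preset A [phenotype_preset()].
#' @param duration Recording length, seconds.
#' @param sampling_interval Sampling interval, ms (5 or 10 in the emulated
#'   plate reader; any positive value accepted).
#' @param seed Integer well seed.
#' @param event `NULL`, or an event descriptor as built by the `event`
#'   argument of [inject_event()].
#' @param well_id,group,drug,concentration,phase Annotations stored on the
#'   trace.
#' @param shape Optional pre-computed [calibrate_preset()] result (saves
#'   recalibration when generating many wells from one preset).
#' @return A [new_trace()] object with attributes `ground_truth` (list:
#'   preset name, true parameter values, realized onsets, event record) and
#'   `noise_free` (the trace before noise, for simulator diagnostics).
#' @examples
#' tr <- generate_trace(am_preset(), duration = 10, seed = 1)
#' length(attr(tr, "ground_truth")$onsets)
#' @export
generate_trace <- function(preset, duration = 30, sampling_interval = 5,
                           seed = 1L, event = NULL,
                           well_id = "A1", group = preset$name,
                           drug = NA_character_, concentration = NA_real_,
                           phase = NA_character_, shape = NULL) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be positive (seconds)", call. = FALSE)
  }
  if (!is.numeric(sampling_interval) || sampling_interval <= 0) {
    stop("sampling_interval must be positive (ms)", call. = FALSE)
  }
  validate_preset(preset)
  event <- validate_event(event, duration)
  # the beat shape is continuous; calibrate it on a grid no coarser than 5 ms
  # (a sampler coarser than the knot spacing cannot pin durations to 1 ms)
  if (is.null(shape)) shape <- calibrate_preset(preset, min(sampling_interval, 5))

  dt <- sampling_interval / 1000
  n <- floor(duration / dt) + 1L
  t <- (seq_len(n) - 1L) * dt

  ibi_mean <- 60 / preset$beat_rate
  cv <- if (identical(event$type, "irregular")) event$cv else preset$rate_jitter_cv
  n_draw <- ceiling(duration / ibi_mean * 3) + 20L
  z <- draw_stream(seed, STREAM_IBI, n_draw)
  u_evt <- draw_stream(seed, STREAM_EVENT, n_draw, "unif")

  ibi_floor <- (shape$support[2] - shape$support[1] + 10) / 1000
  ibis <- pmax(ibi_mean * (1 + cv * z), ibi_floor)
  onsets <- 0.15 + c(0, cumsum(ibis))
  keep <- onsets + shape$support[2] / 1000 + 0.02 <= duration
  onsets <- onsets[keep]
  u_evt <- u_evt[seq_along(onsets)]
  if (identical(event$type, "arrest")) {
    live <- onsets < event$onset
    onsets <- onsets[live]
    u_evt <- u_evt[live]
  }

  affected <- rep(FALSE, length(onsets))
  if (identical(event$type, "EAD") && length(onsets)) {
    affected <- u_evt < event$affect_fraction
    if (!any(affected)) affected[1] <- TRUE   # at least one beat carries the bump
  }

  clean <- rep(0, n)
  apd <- preset$apd_targets
  bump_centre <- if (identical(event$type, "EAD")) {
    stats::approx(PWD_FRACTIONS, apd, xout = event$phase, rule = 2)$y
  } else NA_real_
  bump_scale <- if (identical(event$type, "EAD")) {
    ead_bump_scale(shape, bump_centre, event$bump)
  } else NA_real_
  for (i in seq_along(onsets)) {
    s_ms <- (t - onsets[i]) * 1000
    idx <- which(s_ms >= shape$support[1] & s_ms <= shape$support[2])
    if (!length(idx)) next
    w <- render_beat(shape, s_ms[idx])
    if (affected[i]) {
      w <- w + bump_scale * ead_bump_shape(s_ms[idx] - bump_centre)
    }
    clean[idx] <- clean[idx] + w
  }
  clean <- preset$baseline_level + preset$amplitude * clean
  drift <- pmax(1 - preset$drift_rate * t / 60, 0)
  clean <- clean * drift

  noise <- draw_stream(seed, STREAM_NOISE, n) * preset$noise_sd * preset$amplitude
  signal <- clean + noise

  tr <- new_trace(well_id = well_id, time = t, signal = signal,
                  sampling_interval = sampling_interval,
                  group = group, drug = drug,
                  concentration = concentration, phase = phase)
  realized_cv <- if (length(onsets) >= 3) {
    d <- diff(onsets); stats::sd(d) / mean(d)
  } else NA_real_
  gt <- list(
    preset_name = preset$name,
    beat_rate = preset$beat_rate,
    apd_targets = preset$apd_targets,
    capd_targets = preset$capd_targets,
    amplitude = preset$amplitude,
    baseline_level = preset$baseline_level,
    v_up_max = unname(true_slopes(shape, preset$amplitude, sampling_interval)["up"]),
    v_down_max = unname(true_slopes(shape, preset$amplitude, sampling_interval)["down"]),
    onsets = onsets,
    realized_ibi_cv = realized_cv,
    event = c(event, list(affected_beats = which(affected))),
    seed = seed
  )
  attr(tr, "ground_truth") <- gt
  attr(tr, "noise_free") <- clean
  attr(tr, "sim_meta") <- list(preset = preset, duration = duration,
                               sampling_interval = sampling_interval,
                               seed = seed, shape = shape)
  tr
}

# True maximum upstroke / decay velocities of the noise-free beat as seen by
# a sampler at interval dt_ms: the first-difference slope depends on the
# sampling phase, so the ground truth is the phase average of the per-phase
# maximum windowed slope (units/s). Beats in a trace realize quasi-uniform
# phases, so their measured mean converges to this value.
true_slopes <- function(shape, amplitude, dt_ms = 5) {
  fine <- 0.05
  s <- seq(shape$support[1] - dt_ms, shape$support[2] + dt_ms, by = fine)
  w <- render_beat(shape, s) * amplitude
  k <- round(dt_ms / fine)
  D <- (w[(k + 1):length(w)] - w[1:(length(w) - k)]) / (dt_ms / 1000)
  n_phase <- k
  up <- numeric(n_phase)
  down <- numeric(n_phase)
  for (ph in seq_len(n_phase)) {
    idx <- seq(ph, length(D), by = k)
    up[ph] <- max(D[idx])
    down[ph] <- max(-D[idx])
  }
  c(up = mean(up), down = mean(down))
}

# Unit-amplitude EAD transient: a rapid secondary depolarization (3-ms
# logistic rise) with a slower decay (25-ms exponential), peaking at s = 0.
# EADs are depolarizing events, so the asymmetric fast-up/slow-down shape is
# the physiologic minimal morphology; it also survives the analysis-side
# smoothing that a symmetric narrow bump would not.
ead_bump_shape <- function(s_ms) {
  raw <- function(u) stats::plogis(u / 3) * exp(-pmax(u, 0) / 25)
  u_pk <- stats::optimize(function(u) -raw(u), c(-10, 30))$minimum
  raw(s_ms + u_pk) / raw(u_pk)
}

# The requested EAD "bump" parameter is the PROMINENCE of the secondary
# maximum on the noise-free waveform (fraction of beat amplitude): the raw
# transient is scaled so that the rise from the pre-bump dip to the secondary
# peak equals the request. On a declining repolarization limb an unscaled
# transient would realize well under its nominal height, which would make
# injected ground truth and detector evidence incommensurable.
ead_bump_scale <- function(shape, centre_ms, bump) {
  s <- seq(centre_ms - 80, centre_ms + 50, by = 0.25)
  env <- render_beat(shape, s)
  bs <- ead_bump_shape(s - centre_ms)
  rise <- function(lambda) {
    y <- env + lambda * bs
    run_min <- cummin(y)
    max(y - run_min)
  }
  target <- bump
  f <- function(lambda) rise(lambda) - target
  if (f(6 * bump) < 0) return(6 * bump)   # steep limb: cap the scaling
  stats::uniroot(f, lower = 1e-4, upper = 6 * bump, tol = 1e-6)$root
}

validate_event <- function(event, duration) {
  if (is.null(event)) return(list(type = "none"))
  if (is.character(event)) event <- list(type = event)
  type <- match.arg(event$type, c("none", "EAD", "irregular", "arrest"))
  if (type == "EAD") {
    bump <- event$bump %||% 0.10
    phase <- event$phase %||% 0.5
    affect <- event$affect_fraction %||% 0.5
    if (bump <= 0 || bump >= 1) stop("EAD bump fraction must be in (0, 1)", call. = FALSE)
    if (phase <= 0.3 || phase >= 0.9) {
      stop("EAD bump phase must be a repolarization fraction in (0.3, 0.9)", call. = FALSE)
    }
    if (affect <= 0 || affect > 1) stop("EAD affect_fraction must be in (0, 1]", call. = FALSE)
    return(list(type = "EAD", bump = bump, phase = phase, affect_fraction = affect))
  }
  if (type == "irregular") {
    cv <- event$cv %||% 0.30
    if (cv < 0) stop("irregular IBI CV must be >= 0", call. = FALSE)
    return(list(type = "irregular", cv = cv))
  }
  if (type == "arrest") {
    onset <- event$onset %||% 0
    if (onset > duration) stop("arrest onset lies beyond the trace end", call. = FALSE)
    return(list(type = "arrest", onset = onset))
  }
  list(type = "none")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inject an arrhythmia-like event into a synthetic trace
#'
#' Re-renders a simulated trace with an early afterdepolarization (EAD),
#' irregular-beating, or arrest event, keeping all other random draws (beat
#' onsets, noise) identical thanks to the counter-based seeding scheme.
#'
#' * `EAD`: adds a Gaussian-shaped positive deflection on the repolarization
#'   limb of affected beats (`bump` fraction of amplitude, centred where
#'   repolarization reaches `phase`, on a random `affect_fraction` of beats).
#' * `irregular`: redraws beat onsets with inter-beat-interval coefficient of
#'   variation `cv` (the same standard-normal draws are reused, so requesting
#'   the preset's own jitter CV reproduces the un-injected trace).
#' * `arrest`: removes all beats from `onset` (seconds) onwards, leaving
#'   baseline, drift and noise.
#'
#' @param trace A trace produced by [generate_trace()].
#' @param event Event type: `"EAD"`, `"irregular"` or `"arrest"`.
#' @param ... Event parameters (`bump`, `phase`, `affect_fraction`; `cv`;
#'   `onset`), see Details.
#' @return A new trace with updated ground truth.
#' @examples
#' tr <- generate_trace(ct_preset(), duration = 10, seed = 3)
#' tr_ead <- inject_event(tr, "EAD", bump = 0.1, phase = 0.5)
#' @export
inject_event <- function(trace, event = c("EAD", "irregular", "arrest"), ...) {
  meta <- attr(trace, "sim_meta")
  if (is.null(meta)) {
    stop("inject_event() needs a trace produced by generate_trace()", call. = FALSE)
  }
  event <- match.arg(event)
  generate_trace(meta$preset, duration = meta$duration,
                 sampling_interval = meta$sampling_interval,
                 seed = meta$seed,
                 event = c(list(type = event), list(...)),
                 well_id = trace$well_id, group = trace$group,
                 drug = trace$drug, concentration = trace$concentration,
                 phase = trace$phase, shape = meta$shape)
}
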