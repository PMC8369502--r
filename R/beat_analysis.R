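# --- small internal signal utilities -----------------------------------------

moving_average <- function(x, k) {
  if (k <= 1) return(x)
  out <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  out[is.na(out)] <- x[is.na(out)]
  out
}

# Noise SD estimated from a low quantile of the absolute first differences:
# beat-driven differences contaminate the upper part of the distribution, but
# the diastolic segments (>20 % of any analyzable trace) pin the 20 %
# quantile to the noise floor. For Gaussian noise |diff| has quantile
# 0.2533 * sd(diff) at probability 0.2, and sd(diff) = sqrt(2) * sd(noise).
robust_noise_sd <- function(x) {
  q <- stats::quantile(abs(diff(x)), probs = 0.2, names = FALSE, type = 7)
  q / (0.2533 * sqrt(2))
}

local_maxima <- function(x) {
  d <- diff(x)
  which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
}

# Topographic prominence of each peak: height above the higher of the two
# minima separating it from the nearest strictly taller samples (or edges).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    l <- p
    left_min <- h
    while (l > 1L) {
      l <- l - 1L
      if (x[l] > h) break
      if (x[l] < left_min) left_min <- x[l]
    }
    r <- p
    right_min <- h
    n <- length(x)
    while (r < n) {
      r <- r + 1L
      if (x[r] > h) break
      if (x[r] < right_min) right_min <- x[r]
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

# --- detrending ---------------------------------------------------------------

#' Estimate the dominant beat period of a trace
#'
#' Autocorrelation-based period estimate used to size the detrending window.
#' Returns `NA` when no credible periodicity is found (e.g. arrested wells).
#'
#' @param signal Numeric signal.
#' @param dt Sample interval, seconds.
#' @return Period in seconds, or `NA`.
#' @export
estimate_period <- function(signal, dt) {
  n <- length(signal)
  lag_max <- min(n - 2L, round(3 / dt))
  min_lag <- max(2L, round(0.1 / dt))
  if (lag_max <= min_lag) return(NA_real_)
  a <- stats::acf(signal, lag.max = lag_max, plot = FALSE,
                  demean = TRUE)$acf[-1]
  cand <- local_maxima(a)
  cand <- cand[cand >= min_lag & a[cand] > 0.15]
  if (!length(cand)) return(NA_real_)
  best <- max(a[cand])
  cand[a[cand] >= 0.8 * best][1] * dt
}

#' Remove slow photobleaching drift from a trace
#'
#' Subtracts a slow baseline estimated as the rolling 10th percentile of the
#' signal over a window of three median beat periods (period from
#' [estimate_period()]; 1 s fallback when the trace is aperiodic), linearly
#' interpolated between evaluation points. Beat morphology above baseline is
#' preserved. Traces shorter than one baseline window pass through with a
#' warning.
#'
#' @param trace A [new_trace()] object.
#' @param quantile Baseline quantile (default 0.1).
#' @return A detrended trace; the removed baseline is attached as attribute
#'   `"baseline"`, and any simulator attributes are carried over.
#' @export
detrend_trace <- function(trace, quantile = 0.1) {
  stopifnot(inherits(trace, "cw_trace"))
  x <- trace$signal
  dt <- trace$sampling_interval / 1000
  n <- length(x)
  period <- estimate_period(x, dt)
  win_s <- if (is.na(period)) 1 else 3 * period
  win <- round(win_s / dt)
  if (win >= n) {
    warning("trace shorter than one baseline window; detrend skipped")
    return(trace)
  }
  half <- max(1L, win %/% 2L)
  stride <- max(1L, win %/% 8L)
  centers <- unique(c(seq(1L, n, by = stride), n))
  q <- vapply(centers, function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    stats::quantile(x[idx], probs = quantile, names = FALSE, type = 7)
  }, numeric(1))
  baseline <- stats::approx(trace$time[centers], q, xout = trace$time,
                            rule = 2)$y
  out <- trace
  out$signal <- x - baseline
  attr(out, "baseline") <- baseline
  for (a in c("ground_truth", "noise_free", "sim_meta")) {
    attr(out, a) <- attr(trace, a)
  }
  out
}

# --- beat detection and measurement -------------------------------------------

#' Detect and measure beats in a (detrended) trace
#'
#' Finds action-potential waveforms and measures each one. Peaks are located
#' by topographic prominence: a first pass with a floor of 5 robust noise SDs
#' bootstraps the beat amplitude scale, the final threshold is 30 % of the
#' median beat prominence, and a refractory lockout of half the median
#' inter-beat interval (floor 100 ms) suppresses secondary maxima. Beats too
#' close to the trace edges for a complete measurement are discarded.
#'
#' Per beat: the activation time is the time of maximum upstroke velocity
#' (argmax of the first differences, refined to sub-sample precision by a
#' parabolic fit when the upstroke is resolved, or pinned to the steep sample
#' for step-like upstrokes); the local diastolic baseline is the median of
#' the 50 ms window ending 20 ms before activation; amplitude is peak minus
#' baseline; `pwdXX` is the time (ms) from activation to the first downstroke
#' crossing of `baseline + (1 - XX/100) * amplitude`, linearly interpolated
#' between samples (with a local linear-regression refinement when
#' measurement noise is appreciable); `v_up_max`/`v_down_max` are the largest
#' rising/falling first differences per second (falling reported positive).
#' Crossings never reached before the next beat yield `NA` for that duration.
#'
#' @param trace A [new_trace()] object, normally after [detrend_trace()].
#' @param prominence_frac Final prominence threshold as a fraction of the
#'   median beat prominence (default 0.3).
#' @param noise_floor_mult First-pass prominence floor in robust noise SDs.
#' @param lockout_frac Refractory lockout as a fraction of the median IBI.
#' @param lockout_min_s Lockout floor, seconds.
#' @return A data.frame of class `beat_table`, one row per beat, with columns
#'   `t_activation`, `t_peak`, `amplitude`, `v_up_max`, `v_down_max`,
#'   `pwd20` ... `pwd95` (ms) and `ibi_prev` (s). Zero rows when no beats are
#'   found (a valid result: arrested wells).
#' @export
detect_beats <- function(trace, prominence_frac = 0.3,
                         noise_floor_mult = 5,
                         lockout_frac = 0.5, lockout_min_s = 0.1) {
  stopifnot(inherits(trace, "cw_trace"))
  x <- trace$signal
  t <- trace$time
  n <- length(x)
  dt <- trace$sampling_interval / 1000

  sigma <- robust_noise_sd(x)
  xs <- if (sigma > 0) moving_average(x, 3L) else x

  cand <- local_maxima(xs)
  empty <- beat_table(NULL)
  if (!length(cand)) return(empty)
  prom <- peak_prominence(xs, cand)
  floor1 <- max(noise_floor_mult * sigma, 1e-12)
  pass1 <- cand[prom >= floor1]
  if (!length(pass1)) return(empty)
  med_prom <- stats::median(prom[prom >= floor1])
  thr <- max(floor1, prominence_frac * med_prom)
  keep <- prom >= thr
  peaks <- cand[keep]
  prom_k <- prom[keep]
  if (!length(peaks)) return(empty)

  med_ibi <- if (length(pass1) >= 2) stats::median(diff(t[pass1])) else Inf
  lockout <- max(lockout_min_s, lockout_frac * med_ibi)
  ord <- order(prom_k, decreasing = TRUE)
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) ||
        all(abs(t[peaks[i]] - t[accepted]) >= lockout)) {
      accepted <- c(accepted, peaks[i])
    }
  }
  peaks <- sort(accepted)

  noisy <- sigma > 0.005 * med_prom
  scan_sig <- if (noisy) xs else x

  rows <- vector("list", length(peaks))
  prev_act_idx <- NULL
  prev_act_t <- NA_real_
  for (bi in seq_along(peaks)) {
    p <- peaks[bi]
    left <- if (bi > 1) peaks[bi - 1] else 1L
    valley <- left + which.min(xs[left:p]) - 1L
    act <- activation_time(x, t, dt, valley, p)
    if (is.null(act)) next
    t_act <- act$t_act
    i_act <- act$i_act

    # local diastolic baseline: median of the 50 ms ending 20 ms before activation
    b_idx <- which(t >= t_act - 0.070 & t <= t_act - 0.020)
    if (length(b_idx) < 2L) next    # clipped at the leading edge
    base <- stats::median(x[b_idx])

    # refine the peak near the detected (smoothed) maximum; under noise the
    # smoothed peak value is used (the raw maximum is an extreme-value
    # statistic and systematically overestimates the amplitude)
    p_idx <- max(1L, p - 2L):min(n, p + 2L)
    p_raw <- p_idx[which.max(x[p_idx])]
    peak_val <- if (sigma > 0.005 * med_prom) xs[p] else x[p_raw]
    amp <- peak_val - base
    if (!is.finite(amp) || amp <= 0) next

    limit <- if (bi < length(peaks)) {
      nxt_valley <- peaks[bi] + which.min(xs[peaks[bi]:peaks[bi + 1]]) - 1L
      nxt_valley
    } else n

    fr <- c(PWD_FRACTIONS, 0.95)
    pwd <- rep(NA_real_, length(fr))
    t_prev_cross <- t[p_raw]
    scan_from <- p_raw
    for (k in seq_along(fr)) {
      level <- base + (1 - fr[k]) * amp
      seg <- scan_sig[scan_from:limit]
      j_rel <- which(seg <= level)
      if (!length(j_rel)) break
      j <- scan_from + j_rel[1] - 1L
      if (j == scan_from) {
        t_cross <- t[j]
      } else if (noisy) {
        den <- scan_sig[j - 1] - scan_sig[j]
        frac <- if (den > 0) (scan_sig[j - 1] - level) / den else 0
        t_cross <- t[j - 1] + frac * dt
        t_cross <- refine_crossing(x, t, t_cross, level, dt,
                                   lo = t_prev_cross, hi = t[limit])
      } else {
        t_cross <- spline_crossing(x, t, j, level, dt)
      }
      t_cross <- max(t_cross, t_prev_cross)
      pwd[k] <- (t_cross - t_act) * 1000
      t_prev_cross <- t_cross
      scan_from <- j
    }
    # clipped at the trailing edge: last beat whose repolarization never
    # completes before the trace ends
    if (bi == length(peaks) && all(is.na(pwd)) && limit == n &&
        scan_sig[n] > base + 0.3 * amp) {
      next
    }

    d_seg <- diff(x[max(1L, valley):p_raw]) / dt
    v_up <- if (length(d_seg)) max(d_seg) else NA_real_
    down_sig <- if (noisy) xs else x
    down_end <- limit
    d_down <- diff(down_sig[p_raw:down_end]) / dt
    v_down <- if (length(d_down)) max(-d_down) else NA_real_

    rows[[bi]] <- data.frame(
      t_activation = t_act, t_peak = t[p_raw], amplitude = amp,
      v_up_max = v_up, v_down_max = v_down,
      as.list(stats::setNames(pwd, paste0("pwd", 100 * fr))),
      ibi_prev = if (is.na(prev_act_t)) NA_real_ else t_act - prev_act_t
    )
    prev_act_t <- t_act
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  beat_table(out, well_id = trace$well_id)
}

beat_table <- function(df, well_id = NA_character_) {
  if (is.null(df) || !nrow(df)) {
    df <- data.frame(
      t_activation = numeric(0), t_peak = numeric(0), amplitude = numeric(0),
      v_up_max = numeric(0), v_down_max = numeric(0)
    )
    for (f in c(PWD_FRACTIONS, 0.95)) df[[paste0("pwd", 100 * f)]] <- numeric(0)
    df$ibi_prev <- numeric(0)
  }
  # ibi_prev recomputed here so subsetting upstream cannot desynchronize it
  if (nrow(df)) df$ibi_prev <- c(NA_real_, diff(df$t_activation))
  df$well_id <- rep(well_id, length.out = nrow(df))
  class(df) <- c("beat_table", "data.frame")
  df
}

# Sub-sample activation-time estimate from the first differences between
# valley and peak. Step-like upstrokes (one dominant difference) pin to the
# steep sample; resolved upstrokes are interpolated with a local cubic spline
# whose derivative is maximized on a fine grid (a parabola through the three
# largest differences is badly biased when the upstroke spans only a couple
# of samples).
activation_time <- function(x, t, dt, valley, p) {
  if (p - valley < 1L) return(NULL)
  j <- (valley + 1L):p
  d <- x[j] - x[j - 1L]
  i_rel <- which.max(d)
  i_star <- j[i_rel]
  d0 <- d[i_rel]
  dm <- if (i_rel > 1L) d[i_rel - 1L] else 0
  dp <- if (i_rel < length(d)) d[i_rel + 1L] else 0
  if (d0 > 3 * max(dm, dp, 0)) {
    return(list(t_act = t[i_star], i_act = i_star))
  }
  lo <- max(valley, i_star - 4L)
  hi <- min(length(x), i_star + 3L)
  if (hi - lo < 3L) {
    return(list(t_act = t[i_star] - dt / 2, i_act = i_star))
  }
  sf <- stats::splinefun(t[lo:hi], x[lo:hi], method = "fmm")
  grid <- seq(t[i_star] - dt, t[i_star], by = dt / 50)
  slope <- sf(grid, deriv = 1)
  list(t_act = grid[which.max(slope)], i_act = i_star)
}

# Sub-sample level crossing on a clean signal: cubic interpolation through
# the samples around the bracketing interval [j-1, j], solved by root
# finding. Falls back to linear interpolation when the bracket is degenerate.
spline_crossing <- function(x, t, j, level, dt) {
  lo <- max(1L, j - 2L)
  hi <- min(length(x), j + 2L)
  lin <- function() {
    den <- x[j - 1] - x[j]
    frac <- if (is.finite(den) && den > 0) (x[j - 1] - level) / den else 0
    t[j - 1] + frac * dt
  }
  if (j < 2L) return(t[j])
  if (hi - lo < 3L) return(lin())
  sf <- stats::splinefun(t[lo:hi], x[lo:hi], method = "fmm")
  f_lo <- sf(t[j - 1]) - level
  f_hi <- sf(t[j]) - level
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo < 0 || f_hi > 0) return(lin())
  stats::uniroot(function(tt) sf(tt) - level,
                 lower = t[j - 1], upper = t[j], tol = 1e-6)$root
}

# Local linear-regression refinement of a level crossing under noise: fit the
# raw signal around the provisional crossing and solve the fitted line for the
# level. Falls back to the provisional estimate for non-decreasing fits.
refine_crossing <- function(x, t, t0, level, dt, lo, hi) {
  # window kept tight: a wide secant fit picks up curvature bias on the
  # convex approach to the late-repolarization tail
  half <- max(0.010, 2 * dt)
  idx <- which(t >= t0 - half & t <= t0 + half)
  if (length(idx) < 3L) return(t0)
  fit <- stats::lm.fit(cbind(1, t[idx] - t0), x[idx])
  b <- fit$coefficients[2]
  if (!is.finite(b) || b >= 0) return(t0)
  t_ref <- t0 + (level - fit$coefficients[1]) / b
  if (t_ref < t0 - half || t_ref > t0 + half) return(t0)
  min(max(t_ref, lo), hi)
}

# --- per-beat derived quantities ---------------------------------------------

#' Plateau ratio of a beat
#'
#' Ratio of the early to the late repolarization interval,
#' `(PWD40 - PWD30) / (PWD80 - PWD70)`: values above 1 indicate a
#' plateau-bearing (ventricular-like) action potential, values below 1 a
#' spike-like (atrial-like) one. A linear repolarization gives exactly 1.
#'
#' @param pwd Either a named numeric vector with elements `pwd30`, `pwd40`,
#'   `pwd70`, `pwd80` (ms), or a `beat_table` row / data.frame with those
#'   columns (then a vector of ratios is returned).
#' @return Dimensionless ratio(s); `NA` where any constituent is undefined.
#' @examples
#' plateau_ratio(c(pwd30 = 230, pwd40 = 256, pwd70 = 330, pwd80 = 350)) # 1.3
#' @export
plateau_ratio <- function(pwd) {
  if (is.data.frame(pwd) || is.list(pwd)) {
    p30 <- pwd$pwd30; p40 <- pwd$pwd40; p70 <- pwd$pwd70; p80 <- pwd$pwd80
  } else {
    p30 <- pwd[["pwd30"]]; p40 <- pwd[["pwd40"]]
    p70 <- pwd[["pwd70"]]; p80 <- pwd[["pwd80"]]
  }
  ratio <- (p40 - p30) / (p80 - p70)
  ratio[!is.finite(ratio)] <- NA_real_
  ratio
}

# --- well summary -------------------------------------------------------------

#' Summarize a well's beats over an analysis window
#'
#' Averages every evaluation parameter over the beats whose activation time
#' falls inside the window (default: the first 30 s). Beat rate is
#' `(n - 1) / (t_last - t_first) * 60` for `n >= 2` beats. Fridericia
#' correction is applied per beat from its preceding inter-beat interval and
#' then averaged (the first beat of a window, lacking an IBI, contributes to
#' uncorrected means only). `pwd30_80` is the late-repolarization width
#' `pwd80cF - pwd30cF` (the uncorrected difference is reported alongside).
#' Beats with an undefined duration are excluded from that duration's mean
#' but still count towards the rate.
#'
#' @param beats A `beat_table` from [detect_beats()].
#' @param window Analysis window: either a scalar `w` (meaning `[0, w]`
#'   seconds) or a length-2 vector `c(start, end)`.
#' @param well_id Well label for the summary (defaults to the beat table's).
#' @return An object of class `well_summary` (a list; see
#'   [as.data.frame.well_summary()]): `n_beats`, `beat_rate`,
#'   `amplitude_mean`, `v_up_mean`, `v_down_mean`, `pwd20`..`pwd90`,
#'   `pwd20cF`..`pwd90cF`, `pwd30_80`, `pwd30_80_unc`, `plateau_ratio`,
#'   `n_pwd_undefined`, `window`.
#' @export
summarize_well <- function(beats, window = 30, well_id = NULL) {
  if (length(window) == 1L) window <- c(0, window)
  if (is.null(well_id)) {
    well_id <- if (nrow(beats)) beats$well_id[1] else NA_character_
  }
  b <- beats[beats$t_activation >= window[1] & beats$t_activation <= window[2], ,
             drop = FALSE]
  n <- nrow(b)
  rate <- if (n >= 2) {
    (n - 1) / (b$t_activation[n] - b$t_activation[1]) * 60
  } else NA_real_

  pwd_cols <- paste0("pwd", 100 * PWD_FRACTIONS)
  mean_or_na <- function(v) if (any(is.finite(v))) mean(v[is.finite(v)]) else NA_real_
  pwd_means <- vapply(pwd_cols, function(cn) mean_or_na(b[[cn]]), numeric(1))

  has_ibi <- is.finite(b$ibi_prev) & b$ibi_prev > 0
  pwd_cf <- vapply(pwd_cols, function(cn) {
    v <- b[[cn]][has_ibi]
    ib <- b$ibi_prev[has_ibi]
    ok <- is.finite(v)
    if (!any(ok)) return(NA_real_)
    mean(fridericia_correct(v[ok], ib[ok]))
  }, numeric(1))
  names(pwd_cf) <- paste0(pwd_cols, "cF")

  ratio <- mean_or_na(plateau_ratio(b))
  n_undef <- sum(!is.finite(as.matrix(b[, pwd_cols, drop = FALSE])))

  out <- structure(
    list(
      well_id = well_id, n_beats = n, beat_rate = rate,
      amplitude_mean = mean_or_na(b$amplitude),
      v_up_mean = mean_or_na(b$v_up_max),
      v_down_mean = mean_or_na(b$v_down_max),
      pwd = pwd_means, pwd_cf = pwd_cf,
      pwd30_80 = unname(pwd_cf["pwd80cF"] - pwd_cf["pwd30cF"]),
      pwd30_80_unc = unname(pwd_means["pwd80"] - pwd_means["pwd30"]),
      plateau_ratio = ratio,
      n_pwd_undefined = n_undef,
      window = window
    ),
    class = "well_summary"
  )
  out
}

#' @export
print.well_summary <- function(x, ...) {
  cat(sprintf("Well %s: %d beats in [%g, %g] s\n",
              x$well_id, x$n_beats, x$window[1], x$window[2]))
  if (x$n_beats == 0) {
    cat("  no beats detected (arrest candidate)\n")
    return(invisible(x))
  }
  cat(sprintf("  beat rate %.1f /min, amplitude %.3f, v_up %.2f, v_down %.2f /s\n",
              x$beat_rate, x$amplitude_mean, x$v_up_mean, x$v_down_mean))
  cat("  PWD   (ms):", paste(sprintf("%s=%.1f", names(x$pwd), x$pwd),
                             collapse = " "), "\n")
  cat("  PWDcF (ms):", paste(sprintf("%s=%.1f", names(x$pwd_cf), x$pwd_cf),
                             collapse = " "), "\n")
  cat(sprintf("  PWD30-80 %.1f ms (uncorrected %.1f), plateau ratio %.2f\n",
              x$pwd30_80, x$pwd30_80_unc, x$plateau_ratio))
  invisible(x)
}

#' Flatten a well summary to a one-row data.frame
#'
#' @param x A `well_summary`.
#' @param ... Unused.
#' @return One-row data.frame with scalar columns (`pwd20`..`pwd90`,
#'   `pwd20cF`..`pwd90cF` expanded).
#' @export
as.data.frame.well_summary <- function(x, ...) {
  df <- data.frame(
    well_id = x$well_id, n_beats = x$n_beats, beat_rate = x$beat_rate,
    amplitude_mean = x$amplitude_mean, v_up_mean = x$v_up_mean,
    v_down_mean = x$v_down_mean, stringsAsFactors = FALSE
  )
  for (nm in names(x$pwd)) df[[nm]] <- unname(x$pwd[nm])
  for (nm in names(x$pwd_cf)) df[[nm]] <- unname(x$pwd_cf[nm])
  df$pwd30_80 <- x$pwd30_80
  df$pwd30_80_unc <- x$pwd30_80_unc
  df$plateau_ratio <- x$plateau_ratio
  df$n_pwd_undefined <- x$n_pwd_undefined
  df$window_start <- x$window[1]
  df$window_end <- x$window[2]
  df
}

# --- one-call analysis of a single trace --------------------------------------

#' Analyze one well's trace end to end
#'
#' Runs the full single-well pipeline: drift removal, beat detection and
#' measurement, 30-s window averaging, and arrhythmia-like event
#' classification.
#'
#' @param trace A [new_trace()] object.
#' @param window Analysis window (see [summarize_well()]).
#' @param detrend Remove photobleaching drift first? Default `TRUE`.
#' @param config Classifier thresholds, see [classifier_config()].
#' @return An object of class `well_analysis` with elements `trace`,
#'   `detrended`, `beats`, `summary` and `event` (an `event_call`), plus
#'   print/summary/plot methods.
#' @examples
#' tr <- generate_trace(am_preset(), duration = 10, seed = 7)
#' fit <- analyze_trace(tr, window = 10)
#' fit
#' @export
analyze_trace <- function(trace, window = 30, detrend = TRUE,
                          config = classifier_config()) {
  td <- if (detrend) detrend_trace(trace) else trace
  beats <- detect_beats(td)
  summ <- summarize_well(beats, window = window, well_id = trace$well_id)
  call <- classify_well(td, beats, summ, config)
  structure(list(trace = trace, detrended = td, beats = beats,
                 summary = summ, event = call),
            class = "well_analysis")
}

#' @export
print.well_analysis <- function(x, ...) {
  print(x$summary)
  cat(sprintf("  event label: %s (IBI CV %.3f, EAD beats %d)\n",
              x$event$label,
              if (is.finite(x$event$evidence$ibi_cv)) x$event$evidence$ibi_cv else NA,
              x$event$evidence$n_ead_beats))
  invisible(x)
}

#' @export
summary.well_analysis <- function(object, ...) object$summary

#' @export
plot.well_analysis <- function(x, ..., show_detrended = TRUE) {
  tr <- if (show_detrended) x$detrended else x$trace
  graphics::plot(tr$time, tr$signal, type = "l", xlab = "time (s)",
                 ylab = "fluorescence (a.u.)",
                 main = sprintf("well %s: %s", tr$well_id, x$event$label), ...)
  if (nrow(x$beats)) {
    graphics::abline(v = x$beats$t_activation, col = "grey70", lty = 3)
    peak_idx <- vapply(x$beats$t_peak, function(tp) {
      which.min(abs(tr$time - tp))
    }, integer(1))
    graphics::points(x$beats$t_peak, tr$signal[peak_idx],
                     col = "red", pch = 20)
  }
  invisible(x)
}
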