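#' Classifier thresholds for arrhythmia-like event calling
#'
#' The plate-reader literature gives no quantitative criteria for these
#' calls, so the thresholds are explicit and configurable:
#'
#' * `ead_prominence_frac`: a repolarization-limb local maximum counts as an
#'   EAD when its prominence is at least this fraction of the beat amplitude
#'   (default 0.05) and at least `ead_noise_mult` smoothed-noise SDs.
#' * `ead_band`: repolarization band searched for EADs (between these decay
#'   fractions; default 30-95 %).
#' * `ead_min_width_samples`: minimum half-prominence width of the secondary
#'   maximum (default 2 samples; rejects single-sample noise spikes).
#' * `min_ead_beats`: EAD-positive beats required before the well is labeled
#'   EAD (default 2; a single flagged beat in a hundred is treated as noise).
#' * `irregular_cv_threshold`: IBI coefficient of variation above which
#'   beating is irregular (default 0.15; scale-free across the CT/AM rate
#'   difference).
#' * `min_beats_for_irregular`: below this beat count irregularity is not
#'   evaluable (default 5).
#' * `arrest_max_beats`: at most this many beats in the analysis window is
#'   called arrest (default 1, tolerating one residual artifact peak).
#' * `ead_smooth_ms`: moving-average window applied before the
#'   secondary-maximum search (default 15 ms, i.e. 3 samples at 5-ms
#'   sampling; kept light so genuine EAD transients are not averaged away).
#'
#' @param ... Named overrides of the defaults above.
#' @return A named list of thresholds.
#' @export
classifier_config <- function(...) {
  cfg <- list(
    ead_prominence_frac = 0.05,
    ead_noise_mult = 3.5,
    ead_band = c(0.30, 0.95),
    ead_min_width_samples = 2L,
    min_ead_beats = 2L,
    irregular_cv_threshold = 0.15,
    min_beats_for_irregular = 5L,
    arrest_max_beats = 1L,
    ead_smooth_ms = 15
  )
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad)) stop("unknown classifier option(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(override)] <- override
  cfg
}

#' Detect early afterdepolarizations on each beat
#'
#' Scans the repolarization limb of every measured beat (between the 30 % and
#' 95 % decay crossings) for a secondary local maximum after light
#' moving-average smoothing. A beat is EAD-positive when such a maximum rises
#' above the
#' preceding local minimum by at least `ead_prominence_frac` of the beat
#' amplitude (and at least `ead_noise_mult` smoothed-noise SDs) with a
#' half-prominence width of at least `ead_min_width_samples`.
#'
#' @param trace The (detrended) trace the beats were measured on.
#' @param beats A `beat_table` from [detect_beats()].
#' @param config See [classifier_config()].
#' @return A list: `flags` (logical per beat), `n_ead_beats`,
#'   `max_prominence` (largest secondary-maximum prominence found, as a
#'   fraction of amplitude).
#' @export
detect_ead <- function(trace, beats, config = classifier_config()) {
  n_beats <- nrow(beats)
  res <- list(flags = logical(n_beats), n_ead_beats = 0L,
              max_prominence = 0)
  if (!n_beats) return(res)
  x <- trace$signal
  t <- trace$time
  dt <- trace$sampling_interval / 1000
  sigma <- robust_noise_sd(x)
  k <- max(3L, round(config$ead_smooth_ms / (1000 * dt)))
  if (k %% 2L == 0L) k <- k + 1L
  xs <- moving_average(x, k)
  sigma_sm <- sigma / sqrt(k)

  lo_f <- config$ead_band[1]
  hi_f <- config$ead_band[2]
  max_prom <- 0
  for (i in seq_len(n_beats)) {
    t_lo <- beats$t_activation[i] + beats[[paste0("pwd", 100 * lo_f)]][i] / 1000
    pwd_hi <- beats[[paste0("pwd", 100 * hi_f)]][i]
    t_hi <- if (is.finite(pwd_hi)) {
      beats$t_activation[i] + pwd_hi / 1000
    } else if (i < n_beats) {
      beats$t_activation[i + 1] - 0.02
    } else {
      t[length(t)]
    }
    if (!is.finite(t_lo) || t_hi - t_lo < 4 * dt) next
    idx <- which(t >= t_lo & t <= t_hi)
    if (length(idx) < 5L) next
    seg <- xs[idx]
    lm_idx <- local_maxima(seg)
    lm_idx <- lm_idx[lm_idx > 1L & lm_idx < length(seg)]
    if (!length(lm_idx)) next
    amp <- beats$amplitude[i]
    thr <- max(config$ead_prominence_frac * amp,
               config$ead_noise_mult * sigma_sm)
    for (m in lm_idx) {
      run_min <- min(seg[1:m])
      prom <- seg[m] - run_min
      if (prom > max_prom * amp) max_prom <- prom / amp
      if (prom < thr) next
      above <- seg > seg[m] - prom / 2
      l <- m; while (l > 1L && above[l - 1L]) l <- l - 1L
      r <- m; while (r < length(seg) && above[r + 1L]) r <- r + 1L
      if (r - l + 1L < config$ead_min_width_samples) next
      res$flags[i] <- TRUE
      break
    }
  }
  res$n_ead_beats <- sum(res$flags)
  res$max_prominence <- max_prom
  res
}

#' Detect irregular beating from inter-beat intervals
#'
#' Computes the coefficient of variation (CV) of the inter-beat intervals and
#' flags the well when it exceeds the configured threshold. With fewer than
#' `min_beats_for_irregular` beats the call is not evaluable (`flag = NA`).
#'
#' @param beats A `beat_table`.
#' @param config See [classifier_config()].
#' @return A list: `flag` (`TRUE`/`FALSE`/`NA`), `ibi_cv`.
#' @export
detect_irregular <- function(beats, config = classifier_config()) {
  ibis <- beats$ibi_prev[is.finite(beats$ibi_prev)]
  if (nrow(beats) < config$min_beats_for_irregular || length(ibis) < 2L) {
    return(list(flag = NA, ibi_cv = NA_real_))
  }
  cv <- stats::sd(ibis) / mean(ibis)
  list(flag = cv > config$irregular_cv_threshold, ibi_cv = cv)
}

#' Detect arrest (cessation of beating)
#'
#' A well is arrested when at most `arrest_max_beats` beats are detected in
#' the analysis window (default 1: fewer than two beats means no measurable
#' rhythm).
#'
#' @param summary A [summarize_well()] result.
#' @param config See [classifier_config()].
#' @return Logical flag.
#' @export
detect_arrest <- function(summary, config = classifier_config()) {
  summary$n_beats <= config$arrest_max_beats
}

#' Classify a well's recording
#'
#' Runs the three event detectors and assigns exactly one label with priority
#' `arrest > EAD > irregular > normal` (a well that stops beating is arrest
#' even if earlier beats carried EADs, mirroring mutually exclusive incidence
#' reporting).
#'
#' @param trace The (detrended) trace.
#' @param beats A `beat_table`.
#' @param summary A [summarize_well()] result.
#' @param config See [classifier_config()].
#' @return An object of class `event_call`: `well_id`, `label` (one of
#'   `"normal"`, `"irregular"`, `"EAD"`, `"arrest"`) and `evidence` (IBI CV,
#'   EAD beat count, beat count, max secondary prominence).
#' @export
classify_well <- function(trace, beats, summary,
                          config = classifier_config()) {
  arrest <- detect_arrest(summary, config)
  ead <- if (!arrest) detect_ead(trace, beats, config) else
    list(flags = logical(0), n_ead_beats = 0L, max_prominence = 0)
  irr <- detect_irregular(beats, config)
  label <- if (arrest) {
    "arrest"
  } else if (ead$n_ead_beats >= config$min_ead_beats) {
    "EAD"
  } else if (isTRUE(irr$flag)) {
    "irregular"
  } else {
    "normal"
  }
  structure(
    list(well_id = summary$well_id, label = label,
         evidence = list(ibi_cv = irr$ibi_cv,
                         n_ead_beats = ead$n_ead_beats,
                         n_beats = summary$n_beats,
                         max_secondary_prominence = ead$max_prominence)),
    class = "event_call"
  )
}

#' @export
print.event_call <- function(x, ...) {
  cat(sprintf("Well %s: %s (beats %d, IBI CV %s, EAD beats %d, max 2nd prom %.3f)\n",
              x$well_id, x$label, x$evidence$n_beats,
              ifelse(is.finite(x$evidence$ibi_cv),
                     sprintf("%.3f", x$evidence$ibi_cv), "NA"),
              x$evidence$n_ead_beats, x$evidence$max_secondary_prominence))
  invisible(x)
}

#' Tabulate event incidence per condition
#'
#' Counts each event label per (drug, group, concentration) condition with
#' its denominator, in deterministic row order (drug, group, ascending
#' concentration).
#'
#' @param calls A list of `event_call` objects or a data.frame with columns
#'   `well_id`, `label`.
#' @param plate_map Data.frame with columns `well`, `group`, `drug`,
#'   `concentration_uM` (extra columns ignored; `phase` rows other than
#'   `"post"` are dropped if present).
#' @return Data.frame with columns `drug`, `group`, `concentration_uM`, `n`,
#'   `n_irregular`, `n_ead`, `n_arrest`.
#' @export
incidence_table <- function(calls, plate_map) {
  if (!is.data.frame(calls)) {
    calls <- data.frame(
      well_id = vapply(calls, function(c) c$well_id, character(1)),
      label = vapply(calls, function(c) c$label, character(1)),
      stringsAsFactors = FALSE
    )
  }
  pm <- plate_map
  if ("phase" %in% names(pm)) pm <- pm[pm$phase == "post" | is.na(pm$phase), ]
  pm <- unique(pm[, c("well", "group", "drug", "concentration_uM")])
  m <- merge(calls, pm, by.x = "well_id", by.y = "well", all.x = TRUE)
  if (any(is.na(m$group))) {
    stop("wells missing from the plate map: ",
         paste(m$well_id[is.na(m$group)], collapse = ", "), call. = FALSE)
  }
  key <- interaction(m$drug, m$group, m$concentration_uM, drop = TRUE)
  tab <- do.call(rbind, lapply(split(m, key), function(g) {
    data.frame(
      drug = g$drug[1], group = g$group[1],
      concentration_uM = g$concentration_uM[1],
      n = nrow(g),
      n_irregular = sum(g$label == "irregular"),
      n_ead = sum(g$label == "EAD"),
      n_arrest = sum(g$label == "arrest"),
      stringsAsFactors = FALSE
    )
  }))
  tab <- tab[order(tab$drug, tab$group, tab$concentration_uM), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
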