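#' Repolarization fractions at which durations are measured
#'
#' The pulse-width durations tracked throughout the package are measured at
#' these decay fractions (20, 30, 40, 50, 70, 80 and 90 % of the way from
#' peak back to baseline).
#' @format Numeric vector of length 7.
#' @export
PWD_FRACTIONS <- c(0.20, 0.30, 0.40, 0.50, 0.70, 0.80, 0.90)

#' Construct a cardiomyocyte phenotype preset
#'
#' A phenotype preset parameterizes the synthetic optical-trace generator for
#' one cardiomyocyte subtype: spontaneous beat rate, the action-potential
#' duration profile, waveform amplitude and upstroke kinetics, plus the
#' nuisance components of a plate recording (measurement noise, photobleaching
#' drift, beat-to-beat rate jitter).
#'
#' Plate readers report rate-corrected durations, so the duration profile is
#' supplied on the corrected scale (`capd_targets`); the uncorrected durations
#' actually generated at the preset's spontaneous rate are obtained by
#' inverting the Fridericia correction at the preset's mean inter-beat
#' interval and stored in `$apd_targets`.
#'
#' @param name Label for the preset (e.g. `"CT"`, `"AM"`).
#' @param beat_rate Spontaneous rate, beats per minute.
#' @param capd_targets Named numeric vector of rate-corrected durations (ms)
#'   at the repolarization fractions [PWD_FRACTIONS]; names are the fractions.
#'   Must be strictly increasing in fraction.
#' @param amplitude Beat amplitude, arbitrary fluorescence units (> 0).
#' @param upstroke_tau Logistic upstroke time constant, ms.
#' @param baseline_level Diastolic fluorescence baseline, arbitrary units.
#' @param noise_sd Gaussian measurement noise, as a fraction of `amplitude`.
#' @param drift_rate Photobleaching decay, as a fraction of signal per minute
#'   (applied multiplicatively to baseline and beats).
#' @param rate_jitter_cv Coefficient of variation of inter-beat intervals.
#' @return An object of class `phenotype_preset`.
#' @examples
#' p <- ct_preset()
#' p
#' p$apd_targets   # uncorrected generation targets, ms
#' @export
phenotype_preset <- function(name,
                             beat_rate,
                             capd_targets,
                             amplitude = 1,
                             upstroke_tau = 6,
                             baseline_level = 10,
                             noise_sd = 0.02,
                             drift_rate = 0.02,
                             rate_jitter_cv = 0.02) {
  stopifnot(is.character(name), length(name) == 1L)
  capd_targets <- as.numeric(capd_targets)
  if (length(capd_targets) != length(PWD_FRACTIONS)) {
    stop("'capd_targets' must supply one duration per fraction in PWD_FRACTIONS",
         call. = FALSE)
  }
  names(capd_targets) <- format(PWD_FRACTIONS)
  ibi <- 60 / beat_rate
  apd_targets <- fridericia_uncorrect(capd_targets, ibi)
  names(apd_targets) <- names(capd_targets)
  preset <- structure(
    list(
      name = name,
      beat_rate = beat_rate,
      capd_targets = capd_targets,
      apd_targets = apd_targets,
      amplitude = amplitude,
      upstroke_tau = upstroke_tau,
      baseline_level = baseline_level,
      noise_sd = noise_sd,
      drift_rate = drift_rate,
      rate_jitter_cv = rate_jitter_cv
    ),
    class = "phenotype_preset"
  )
  validate_preset(preset)
  preset
}

validate_preset <- function(p) {
  if (!is.finite(p$beat_rate) || p$beat_rate <= 0) {
    stop("beat_rate must be positive", call. = FALSE)
  }
  if (any(diff(p$apd_targets) <= 0)) {
    stop("apd_targets must be strictly increasing across repolarization fractions",
         call. = FALSE)
  }
  if (max(p$apd_targets) >= 60000 / p$beat_rate) {
    stop("APD90 must be shorter than the beat period (60000/beat_rate ms); ",
         "beats would overlap", call. = FALSE)
  }
  if (p$amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (p$upstroke_tau <= 0) stop("upstroke_tau must be > 0", call. = FALSE)
  if (p$rate_jitter_cv < 0) stop("rate_jitter_cv must be >= 0", call. = FALSE)
  if (p$drift_rate < 0) stop("drift_rate must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.phenotype_preset <- function(x, ...) {
  cat("Phenotype preset:", x$name, "\n")
  cat(sprintf("  beat rate      : %.1f /min (IBI %.1f ms)\n",
              x$beat_rate, 60000 / x$beat_rate))
  cat("  cAPD targets   :",
      paste(sprintf("%s%%=%.1f", 100 * PWD_FRACTIONS, x$capd_targets),
            collapse = " "), "ms\n")
  cat("  APD (uncorr.)  :",
      paste(sprintf("%s%%=%.1f", 100 * PWD_FRACTIONS, x$apd_targets),
            collapse = " "), "ms\n")
  cat(sprintf("  amplitude %.2f, upstroke tau %.1f ms, baseline %.2f\n",
              x$amplitude, x$upstroke_tau, x$baseline_level))
  cat(sprintf("  noise %.3f, drift %.3f/min, IBI jitter CV %.3f\n",
              x$noise_sd, x$drift_rate, x$rate_jitter_cv))
  invisible(x)
}

#' Default ventricular-like (control) preset
#'
#' Control hiPSC-cardiomyocyte preparations beat slowly (83.7/min) with a
#' plateau-bearing action potential: corrected APD20/50/90 of 159.8, 315.5 and
#' 369.7 ms and an early/late repolarization interval ratio
#' (APD40-APD30)/(APD80-APD70) of 1.30. The corrected durations at the
#' unreported intermediate fractions (30, 40, 70, 80 %) are fixed at 230, 256,
#' 330 and 350 ms: monotone between the reported values and realizing the
#' plateau ratio exactly.
#'
#' @param ... Overrides passed on to [phenotype_preset()].
#' @return A `phenotype_preset`.
#' @export
ct_preset <- function(...) {
  args <- list(
    name = "CT",
    beat_rate = 83.7,
    capd_targets = c(159.8, 230, 256, 315.5, 330, 350, 369.7),
    upstroke_tau = 6
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(phenotype_preset, args)
}

#' Default atrial-like preset
#'
#' Retinoic-acid-treated (atrial-like) preparations beat fast (237/min) with a
#' spike-like action potential lacking a plateau: corrected APD20/50/90 of
#' 69.8, 114.9 and 156.1 ms and interval ratio 0.75. Intermediate fractions
#' fixed at 85, 97 (30, 40 %) and 130, 146 ms (70, 80 %).
#'
#' @param ... Overrides passed on to [phenotype_preset()].
#' @return A `phenotype_preset`.
#' @export
am_preset <- function(...) {
  args <- list(
    name = "AM",
    beat_rate = 237,
    capd_targets = c(69.8, 85, 97, 114.9, 130, 146, 156.1),
    upstroke_tau = 3
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(phenotype_preset, args)
}

#' Look up the default preset for a group label
#'
#' @param group `"CT"` or `"AM"`.
#' @return A `phenotype_preset`.
#' @export
default_preset <- function(group) {
  switch(as.character(group),
         CT = ct_preset(),
         AM = am_preset(),
         stop("unknown group '", group, "'; expected 'CT' or 'AM'",
              call. = FALSE))
}
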