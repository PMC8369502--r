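#' Define a phenomenological drug-effect model
#'
#' A drug-effect model maps concentration to multiplicative changes of the
#' simulator's phenotype parameters through Hill curves, and (optionally)
#' to expected incidences of arrhythmia-like events per condition. It is
#' phenomenological by design: no ion-channel kinetics, just the
#' concentration-dependent parameter scalings needed to emulate plate-level
#' dose-response behaviour.
#'
#' Each effect is a list with fields:
#' \describe{
#'   \item{target}{one of `"beat_rate"`, `"upstroke_velocity"`,
#'     `"decay_velocity"`, `"apd_scale"` (common scale on all APD targets).}
#'   \item{direction}{`"increase"` or `"decrease"`.}
#'   \item{emax}{maximum fractional change (>= 0; < 1 for decreases).}
#'   \item{ec50}{half-maximal concentration, uM (> 0).}
#'   \item{hill}{Hill coefficient (> 0), default 1.}
#' }
#'
#' @param drug_name Label.
#' @param effects List of effect descriptors (see Details).
#' @param event_incidence Optional data.frame with columns
#'   `concentration_uM`, `group`, `irregular`, `ead`, `arrest` giving expected
#'   per-well event fractions (each in `[0,1]`, summing to <= 1 per row).
#' @return An object of class `drug_effect_model`.
#' @examples
#' m <- drug_effect_model("ikr_blocker", list(
#'   list(target = "beat_rate", direction = "decrease", emax = 0.4, ec50 = 1),
#'   list(target = "apd_scale", direction = "increase", emax = 0.5, ec50 = 1)))
#' @export
drug_effect_model <- function(drug_name, effects = list(),
                              event_incidence = NULL) {
  targets <- c("beat_rate", "upstroke_velocity", "decay_velocity", "apd_scale")
  effects <- lapply(effects, function(e) {
    e$target <- match.arg(e$target, targets)
    e$direction <- match.arg(e$direction, c("increase", "decrease"))
    e$hill <- e$hill %||% 1
    if (is.null(e$emax) || e$emax < 0) stop("emax must be >= 0", call. = FALSE)
    if (e$direction == "decrease" && e$emax >= 1) {
      stop("emax must be < 1 for a decrease (scale would become non-positive)",
           call. = FALSE)
    }
    if (is.null(e$ec50) || e$ec50 <= 0) stop("ec50 must be > 0", call. = FALSE)
    if (e$hill <= 0) stop("hill coefficient must be > 0", call. = FALSE)
    e
  })
  if (!is.null(event_incidence)) {
    need <- c("concentration_uM", "group", "irregular", "ead", "arrest")
    if (!all(need %in% names(event_incidence))) {
      stop("event_incidence needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    frac <- as.matrix(event_incidence[, c("irregular", "ead", "arrest")])
    if (any(frac < 0) || any(frac > 1) || any(rowSums(frac) > 1 + 1e-9)) {
      stop("event fractions must lie in [0,1] and sum to <= 1 per condition",
           call. = FALSE)
    }
  }
  structure(list(drug_name = drug_name, effects = effects,
                 event_incidence = event_incidence),
            class = "drug_effect_model")
}

#' @export
print.drug_effect_model <- function(x, ...) {
  cat("Drug effect model:", x$drug_name, "\n")
  for (e in x$effects) {
    cat(sprintf("  %s: %s, Emax %.2f, EC50 %g uM, Hill %.2f\n",
                e$target, e$direction, e$emax, e$ec50, e$hill))
  }
  if (!is.null(x$event_incidence)) {
    cat("  event incidence table:", nrow(x$event_incidence), "conditions\n")
  }
  invisible(x)
}

hill_fraction <- function(concentration, ec50, hill) {
  ifelse(concentration <= 0, 0,
         concentration^hill / (concentration^hill + ec50^hill))
}

#' Apply a drug-effect model to a phenotype preset
#'
#' Scales each targeted parameter by `1 +/- emax * c^h / (c^h + EC50^h)`.
#' Concentration 0 returns the preset unchanged; the applied effect is
#' monotone in concentration. Velocity targets act on kinetics: an upstroke
#' velocity decrease slows the logistic upstroke (scales its time constant
#' up); a decay velocity decrease stretches all APD targets (durations scale
#' inversely with decay velocity).
#'
#' @param preset A [phenotype_preset()].
#' @param model A [drug_effect_model()].
#' @param concentration Concentration in uM (>= 0).
#' @return A new `phenotype_preset` with post-effect parameters.
#' @examples
#' m <- drug_effect_model("x", list(
#'   list(target = "beat_rate", direction = "decrease", emax = 0.5, ec50 = 1)))
#' apply_drug_effect(ct_preset(), m, 1)$beat_rate  # 83.7 * (1 - 0.25)
#' @export
apply_drug_effect <- function(preset, model, concentration) {
  stopifnot(inherits(preset, "phenotype_preset"),
            inherits(model, "drug_effect_model"))
  if (!is.numeric(concentration) || concentration < 0) {
    stop("concentration must be >= 0", call. = FALSE)
  }
  rate <- preset$beat_rate
  tau <- preset$upstroke_tau
  capd <- preset$capd_targets
  for (e in model$effects) {
    frac <- e$emax * hill_fraction(concentration, e$ec50, e$hill)
    scale <- if (e$direction == "increase") 1 + frac else 1 - frac
    if (e$target == "beat_rate") rate <- rate * scale
    if (e$target == "upstroke_velocity") tau <- tau / scale
    if (e$target == "decay_velocity") capd <- capd / scale
    if (e$target == "apd_scale") capd <- capd * scale
  }
  phenotype_preset(
    name = preset$name, beat_rate = rate, capd_targets = capd,
    amplitude = preset$amplitude, upstroke_tau = tau,
    baseline_level = preset$baseline_level, noise_sd = preset$noise_sd,
    drift_rate = preset$drift_rate, rate_jitter_cv = preset$rate_jitter_cv
  )
}

#' Expected event counts for a condition
#'
#' Converts a model's expected event fractions into deterministic well counts
#' for an `n`-well condition (rounded, assigned in the order irregular, EAD,
#' arrest). Useful to build plate configurations that realize a prescribed
#' incidence exactly.
#'
#' @param model A [drug_effect_model()] with an `event_incidence` table.
#' @param concentration,group Condition selectors.
#' @param n Number of wells.
#' @return Named integer vector `c(irregular=, ead=, arrest=)`.
#' @export
expected_event_counts <- function(model, concentration, group, n) {
  tab <- model$event_incidence
  if (is.null(tab)) return(c(irregular = 0L, ead = 0L, arrest = 0L))
  row <- tab[tab$concentration_uM == concentration & tab$group == group, ]
  if (!nrow(row)) return(c(irregular = 0L, ead = 0L, arrest = 0L))
  counts <- round(n * unlist(row[1, c("irregular", "ead", "arrest")]))
  counts <- pmin(counts, n)
  stats::setNames(as.integer(counts), c("irregular", "ead", "arrest"))
}
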