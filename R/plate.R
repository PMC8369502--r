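#' Generate a simulated multi-well plate
#'
#' Renders one trace per configuration row (a row is one well in one
#' recording phase), assembles the wide trace table, the plate map and the
#' ground-truth table, and optionally writes them to disk. Wells are
#' independent given their seeds.
#'
#' The configuration is a data.frame with required columns `well`, `group`
#' (`"CT"`/`"AM"`), `drug`, `concentration_uM`, `phase` (`"pre"`/`"post"`)
#' and `seed`, plus optional event columns: `event` (`"none"`, `"EAD"`,
#' `"irregular"`, `"arrest"`), `ead_bump`, `ead_phase`, `ead_fraction`,
#' `irr_cv`, `arrest_onset`. Drug effects are applied to post-phase rows with
#' positive concentration when a matching [drug_effect_model()] is supplied.
#'
#' @param config Configuration data.frame (see Details). May have zero rows.
#' @param presets Named list of [phenotype_preset()]s per group label.
#' @param drug_models Optional named list of [drug_effect_model()]s keyed by
#'   drug name.
#' @param duration,sampling_interval Recording length (s) and sampling (ms).
#' @param out_dir If non-`NULL`, the three CSV files are written there (see
#'   [write_plate()]).
#' @return An object of class `cw_plate_sim`: `traces` (named
#'   `<well>_<phase>`), `trace_df` (wide: `time_s` + one column per
#'   well/phase), `plate_map`, `ground_truth`, and the generation settings.
#' @examples
#' cfg <- plate_config(wells = c("A1", "A2"), group = "AM", seeds = 1:2)
#' sim <- generate_plate(cfg, duration = 5)
#' names(sim$traces)
#' @export
generate_plate <- function(config,
                           presets = list(CT = ct_preset(), AM = am_preset()),
                           drug_models = NULL,
                           duration = 30, sampling_interval = 5,
                           out_dir = NULL) {
  need <- c("well", "group", "drug", "concentration_uM", "phase", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("config is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(config$well, config$phase, sep = "_")
  if (anyDuplicated(key)) {
    stop("duplicate well/phase entries in config: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }

  dt <- sampling_interval / 1000
  time_s <- (seq_len(floor(duration / dt) + 1L) - 1L) * dt
  traces <- list()
  gt_rows <- list()
  shape_cache <- list()

  for (i in seq_len(nrow(config))) {
    row <- config[i, ]
    preset <- presets[[as.character(row$group)]]
    if (is.null(preset)) {
      stop("no preset supplied for group '", row$group, "'", call. = FALSE)
    }
    conc <- row$concentration_uM
    if (identical(row$phase, "post") && !is.na(row$drug) &&
        !is.null(drug_models[[row$drug]]) && isTRUE(conc > 0)) {
      preset <- apply_drug_effect(preset, drug_models[[row$drug]], conc)
    }
    cache_key <- paste(row$group, row$phase, row$drug, conc, sep = "|")
    if (is.null(shape_cache[[cache_key]])) {
      shape_cache[[cache_key]] <- calibrate_preset(preset,
                                                   min(sampling_interval, 5))
    }
    event <- config_event(row)
    tr <- generate_trace(preset, duration = duration,
                         sampling_interval = sampling_interval,
                         seed = row$seed, event = event,
                         well_id = as.character(row$well),
                         group = as.character(row$group),
                         drug = as.character(row$drug),
                         concentration = conc,
                         phase = as.character(row$phase),
                         shape = shape_cache[[cache_key]])
    traces[[key[i]]] <- tr
    gt <- attr(tr, "ground_truth")
    gt_rows[[i]] <- data.frame(
      well = as.character(row$well), phase = as.character(row$phase),
      preset = gt$preset_name, group = as.character(row$group),
      drug = as.character(row$drug), concentration_uM = conc,
      seed = row$seed,
      beat_rate_true = gt$beat_rate,
      amplitude_true = gt$amplitude,
      apd90_unc_ms = unname(gt$apd_targets[length(gt$apd_targets)]),
      capd50_ms = unname(gt$capd_targets["0.5"]),
      n_beats_true = length(gt$onsets),
      ibi_cv_realized = gt$realized_ibi_cv,
      event = gt$event$type,
      ead_bump = gt$event$bump %||% NA_real_,
      ead_phase = gt$event$phase %||% NA_real_,
      n_affected = length(gt$event$affected_beats),
      irr_cv = gt$event$cv %||% NA_real_,
      arrest_onset = gt$event$onset %||% NA_real_,
      stringsAsFactors = FALSE
    )
  }

  trace_df <- data.frame(time_s = time_s)
  for (k in names(traces)) trace_df[[k]] <- traces[[k]]$signal

  plate_map <- config[, need, drop = FALSE]
  ground_truth <- if (length(gt_rows)) do.call(rbind, gt_rows) else
    data.frame()
  sim <- structure(
    list(traces = traces, trace_df = trace_df, plate_map = plate_map,
         ground_truth = ground_truth,
         duration = duration, sampling_interval = sampling_interval),
    class = "cw_plate_sim"
  )
  if (!is.null(out_dir)) write_plate(sim, out_dir)
  sim
}

config_event <- function(row) {
  ev <- if ("event" %in% names(row)) as.character(row$event) else "none"
  if (is.na(ev) || ev == "none") return(NULL)
  get_opt <- function(nm) {
    if (nm %in% names(row) && is.finite(row[[nm]])) row[[nm]] else NULL
  }
  switch(ev,
    EAD = list(type = "EAD", bump = get_opt("ead_bump"),
               phase = get_opt("ead_phase"),
               affect_fraction = get_opt("ead_fraction")),
    irregular = list(type = "irregular", cv = get_opt("irr_cv")),
    arrest = list(type = "arrest", onset = get_opt("arrest_onset") %||% 0),
    stop("unknown event type '", ev, "' in config", call. = FALSE)
  )
}

#' Build a plate configuration data.frame
#'
#' Convenience constructor for [generate_plate()] configurations: one pre and
#' one post row per well, sharing the well's seed, with optional per-well
#' post-phase events.
#'
#' @param wells Character vector of well IDs.
#' @param group Group label (recycled), `"CT"` or `"AM"`.
#' @param drug,concentration_uM Condition annotations (recycled).
#' @param seeds Integer seeds, one per well.
#' @param events Character vector of post-phase events per well
#'   (`"none"`, `"EAD"`, `"irregular"`, `"arrest"`; recycled).
#' @param phases Phases to generate, default both.
#' @param ... Extra event-parameter columns (`ead_bump`, `ead_phase`,
#'   `ead_fraction`, `irr_cv`, `arrest_onset`), recycled across wells and
#'   applied to post rows.
#' @return A configuration data.frame.
#' @export
plate_config <- function(wells, group = "CT", drug = NA_character_,
                         concentration_uM = NA_real_, seeds = seq_along(wells),
                         events = "none", phases = c("pre", "post"), ...) {
  nw <- length(wells)
  events <- rep_len(events, nw)
  extra <- list(...)
  rows <- list()
  for (ph in phases) {
    df <- data.frame(
      well = wells, group = rep_len(group, nw),
      drug = rep_len(drug, nw),
      concentration_uM = rep_len(concentration_uM, nw),
      phase = rep_len(ph, nw), seed = rep_len(seeds, nw),
      event = rep_len(if (ph == "post") events else "none", nw),
      stringsAsFactors = FALSE
    )
    for (nm in names(extra)) {
      df[[nm]] <- if (ph == "post") rep_len(extra[[nm]], nw) else
        rep_len(NA_real_, nw)
    }
    rows[[ph]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.cw_plate_sim <- function(x, ...) {
  cat(sprintf("<cw_plate_sim> %d traces, %.0f s at %.0f ms\n",
              length(x$traces), x$duration, x$sampling_interval))
  if (nrow(x$ground_truth)) {
    cat("  events:", paste(sprintf("%s=%d",
        names(table(x$ground_truth$event)),
        as.integer(table(x$ground_truth$event))), collapse = " "), "\n")
  }
  invisible(x)
}
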