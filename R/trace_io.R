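#' Write a simulated plate to CSV files
#'
#' Emits the three plain-text artefacts of a plate recording:
#' `traces.csv` (wide; `time_s` column plus one `<well>_<phase>` column per
#' recording, time in seconds on a uniform grid), `plate_map.csv`
#' (columns `well`, `group`, `drug`, `concentration_uM`, `phase`, `seed`) and
#' `ground_truth.csv` (one row per well/phase with the true simulator
#' parameters and injected event).
#'
#' @param sim A `cw_plate_sim` from [generate_plate()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_plate <- function(sim, out_dir) {
  stopifnot(inherits(sim, "cw_plate_sim"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("traces.csv", "plate_map.csv",
                                "ground_truth.csv"))
  utils::write.csv(sim$trace_df, paths[1], row.names = FALSE)
  utils::write.csv(sim$plate_map, paths[2], row.names = FALSE)
  utils::write.csv(sim$ground_truth, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a plate recording from CSV files
#'
#' Reads the wide trace table and the plate map (formats as written by
#' [write_plate()]) and pairs the pre- and post-compound recordings per well.
#' The time grid must be strictly increasing with a uniform step, every
#' signal value finite, every trace column described by a plate-map row and
#' vice versa, and every post-phase trace matched by a pre-phase trace from
#' the same well (required downstream for percent change).
#'
#' @param trace_csv Path to the wide trace CSV (`time_s`, `<well>_<phase>`
#'   columns).
#' @param plate_map_csv Path to the plate map CSV.
#' @return An object of class `plate_recording`: `wells` (named list, each
#'   with `$pre`/`$post` [new_trace()] objects), `plate_map`,
#'   `sampling_interval` (ms) and `duration` (s).
#' @export
read_plate <- function(trace_csv, plate_map_csv) {
  if (!file.exists(trace_csv)) stop("trace file not found: ", trace_csv, call. = FALSE)
  if (!file.exists(plate_map_csv)) stop("plate map not found: ", plate_map_csv, call. = FALSE)
  td <- utils::read.csv(trace_csv, check.names = FALSE)
  pm <- utils::read.csv(plate_map_csv, stringsAsFactors = FALSE)
  need <- c("well", "group", "drug", "concentration_uM", "phase", "seed")
  miss <- setdiff(setdiff(need, "seed"), names(pm))
  if (length(miss)) {
    stop("plate map is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"time_s" %in% names(td)) {
    stop("trace file has no 'time_s' column", call. = FALSE)
  }
  time <- td$time_s
  steps <- diff(time)
  if (any(steps <= 0) ||
      (length(steps) && max(steps) - min(steps) > 1e-6 * stats::median(steps))) {
    stop("format error: time grid is not strictly increasing and uniform",
         call. = FALSE)
  }
  trace_cols <- setdiff(names(td), "time_s")
  map_keys <- paste(pm$well, pm$phase, sep = "_")
  unmapped <- setdiff(trace_cols, map_keys)
  if (length(unmapped)) {
    stop("mapping error: trace column(s) absent from the plate map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  untraced <- setdiff(map_keys, trace_cols)
  if (length(untraced)) {
    stop("mapping error: plate-map entries with no trace column: ",
         paste(untraced, collapse = ", "), call. = FALSE)
  }

  wells <- list()
  for (i in seq_len(nrow(pm))) {
    key <- map_keys[i]
    sig <- td[[key]]
    if (any(!is.finite(sig))) {
      stop("format error: non-finite signal values in trace ", key,
           call. = FALSE)
    }
    tr <- new_trace(well_id = as.character(pm$well[i]), time = time,
                    signal = sig,
                    group = as.character(pm$group[i]),
                    drug = as.character(pm$drug[i]),
                    concentration = pm$concentration_uM[i],
                    phase = as.character(pm$phase[i]))
    wells[[as.character(pm$well[i])]][[as.character(pm$phase[i])]] <- tr
  }
  lonely <- names(wells)[vapply(wells, function(w) {
    !is.null(w$post) && is.null(w$pre)
  }, logical(1))]
  if (length(lonely)) {
    stop("mapping error: post-phase trace(s) without a matching pre trace: ",
         paste(lonely, collapse = ", "), call. = FALSE)
  }
  structure(
    list(wells = wells, plate_map = pm,
         sampling_interval = stats::median(steps) * 1000,
         duration = time[length(time)] - time[1]),
    class = "plate_recording"
  )
}

#' Convert a simulated plate to a plate recording
#'
#' In-memory equivalent of [write_plate()] followed by [read_plate()]:
#' pairs the simulated traces per well without touching disk.
#'
#' @param sim A `cw_plate_sim`.
#' @return A `plate_recording`.
#' @export
as_plate_recording <- function(sim) {
  stopifnot(inherits(sim, "cw_plate_sim"))
  wells <- list()
  for (k in names(sim$traces)) {
    tr <- sim$traces[[k]]
    wells[[tr$well_id]][[tr$phase]] <- tr
  }
  structure(
    list(wells = wells, plate_map = sim$plate_map,
         sampling_interval = sim$sampling_interval,
         duration = sim$duration),
    class = "plate_recording"
  )
}

#' @export
print.plate_recording <- function(x, ...) {
  cat(sprintf("<plate_recording> %d wells, %.0f s at %.1f ms\n",
              length(x$wells), x$duration, x$sampling_interval))
  invisible(x)
}

#' Write analysis result tables to CSV
#'
#' Writes the per-well summary table (`well_summary.csv`), the percent-change
#' dose-response table (`dose_response.csv`), the event-incidence table
#' (`incidence.csv`) and optionally a statistics table (`stats.csv`).
#' Durations are reported in milliseconds; numeric columns are rounded to
#' 3 decimal places. Empty inputs yield header-only files.
#'
#' @param summaries Data.frame of well summaries (rows from
#'   [as.data.frame.well_summary()]), or a `plate_analysis` object (then the
#'   other tables default to its components).
#' @param dose_response,incidence,stats Optional data.frames.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_results <- function(summaries, dose_response = NULL, incidence = NULL,
                          out_dir, stats = NULL) {
  if (inherits(summaries, "plate_analysis")) {
    pa <- summaries
    summaries <- pa$well_summaries
    dose_response <- dose_response %||% pa$dose_response
    incidence <- incidence %||% pa$incidence
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  round_df <- function(df) {
    if (is.null(df)) return(NULL)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = 3)
    df
  }
  paths <- character(0)
  emit <- function(df, fname) {
    if (is.null(df)) return()
    p <- file.path(out_dir, fname)
    utils::write.csv(round_df(df), p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  emit(summaries, "well_summary.csv")
  emit(dose_response, "dose_response.csv")
  emit(incidence, "incidence.csv")
  emit(stats, "stats.csv")
  invisible(paths)
}
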