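#' Analyze a whole plate recording
#'
#' Runs the single-well pipeline ([analyze_trace()]) on every pre- and
#' post-phase trace, classifies the post-compound recordings, and assembles
#' the plate-level result tables: per-well summaries, percent-change
#' dose-response records and the event-incidence table.
#'
#' @param plate A `plate_recording` from [read_plate()] or
#'   [as_plate_recording()].
#' @param window Analysis window in seconds (see [summarize_well()]).
#' @param config Classifier thresholds, see [classifier_config()].
#' @param parameters Parameters tabulated in the dose-response table.
#' @return An object of class `plate_analysis`: `well_summaries` (data.frame,
#'   one row per well/phase), `event_calls` (post phase), `dose_response`,
#'   `incidence`, `fits` (the underlying `well_analysis` objects, named
#'   `<well>_<phase>`).
#' @examples
#' cfg <- plate_config("A1", group = "AM", seeds = 5)
#' pa <- analyze_plate(as_plate_recording(generate_plate(cfg, duration = 10)),
#'                     window = 10)
#' pa$event_calls
#' @export
analyze_plate <- function(plate, window = 30, config = classifier_config(),
                          parameters = dose_response_parameters()) {
  stopifnot(inherits(plate, "plate_recording"))
  fits <- list()
  summary_rows <- list()
  call_rows <- list()
  for (w in names(plate$wells)) {
    for (ph in names(plate$wells[[w]])) {
      fit <- analyze_trace(plate$wells[[w]][[ph]], window = window,
                           config = config)
      fits[[paste(w, ph, sep = "_")]] <- fit
      row <- as.data.frame(fit$summary)
      row$phase <- ph
      summary_rows[[paste(w, ph, sep = "_")]] <- row
      if (ph == "post") {
        call_rows[[w]] <- data.frame(
          well_id = w, label = fit$event$label,
          ibi_cv = fit$event$evidence$ibi_cv,
          n_ead_beats = fit$event$evidence$n_ead_beats,
          n_beats = fit$event$evidence$n_beats,
          max_secondary_prominence = fit$event$evidence$max_secondary_prominence,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  summaries <- do.call(rbind, summary_rows)
  rownames(summaries) <- NULL
  calls <- do.call(rbind, call_rows)
  if (!is.null(calls)) rownames(calls) <- NULL

  pre <- summaries[summaries$phase == "pre", , drop = FALSE]
  post <- summaries[summaries$phase == "post", , drop = FALSE]
  dr <- NULL
  inc <- NULL
  if (nrow(post) && !is.null(calls)) {
    if (nrow(pre)) {
      dr <- build_dose_response(pre, post, plate$plate_map,
                                parameters = parameters,
                                event_calls = calls)
    }
    inc <- incidence_table(calls, plate$plate_map)
  }
  structure(
    list(well_summaries = summaries, event_calls = calls,
         dose_response = dr, incidence = inc, fits = fits,
         window = window, config = config),
    class = "plate_analysis"
  )
}

#' @export
print.plate_analysis <- function(x, ...) {
  n_wells <- length(unique(x$well_summaries$well_id))
  cat(sprintf("<plate_analysis> %d wells, window [%g, %g] s\n", n_wells,
              0, x$window))
  if (!is.null(x$event_calls)) {
    tab <- table(x$event_calls$label)
    cat("  post-phase labels:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
  if (!is.null(x$incidence)) {
    cat("  incidence rows:", nrow(x$incidence), "\n")
  }
  invisible(x)
}
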