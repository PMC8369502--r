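#' Construct a single-well fluorescence trace
#'
#' A trace is one well's membrane-potential fluorescence time series on a
#' strictly uniform time grid, together with its sampling metadata and
#' optional plate annotations (group, drug, concentration, recording phase).
#'
#' @param well_id Well label, e.g. `"A1"`.
#' @param time Time vector, seconds, strictly increasing with constant step.
#' @param signal Fluorescence values, arbitrary units, finite everywhere.
#' @param sampling_interval Sampling interval in ms; defaults to the grid step.
#' @param group,drug,concentration,phase Optional annotations (`group` one of
#'   `"CT"`/`"AM"`, `phase` one of `"pre"`/`"post"`).
#' @return An object of class `cw_trace`.
#' @export
new_trace <- function(well_id, time, signal,
                      sampling_interval = NULL,
                      group = NA_character_, drug = NA_character_,
                      concentration = NA_real_, phase = NA_character_) {
  time <- as.numeric(time)
  signal <- as.numeric(signal)
  if (length(time) != length(signal)) {
    stop("time and signal must have the same length", call. = FALSE)
  }
  if (length(time) < 2L) stop("trace needs at least two samples", call. = FALSE)
  steps <- diff(time)
  if (any(steps <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (max(steps) - min(steps) > 1e-6 * stats::median(steps)) {
    stop("time grid is not uniform (relative tolerance 1e-6)", call. = FALSE)
  }
  if (any(!is.finite(signal))) {
    stop("signal contains non-finite values", call. = FALSE)
  }
  if (is.null(sampling_interval)) sampling_interval <- stats::median(steps) * 1000
  structure(
    list(well_id = well_id, time = time, signal = signal,
         sampling_interval = sampling_interval,
         group = group, drug = drug,
         concentration = concentration, phase = phase),
    class = "cw_trace"
  )
}

#' @export
print.cw_trace <- function(x, ...) {
  cat(sprintf("<cw_trace> well %s: %.1f s at %.1f ms (%d samples)\n",
              x$well_id, diff(range(x$time)), x$sampling_interval,
              length(x$time)))
  ann <- c(group = x$group, drug = x$drug, phase = x$phase)
  ann <- ann[!is.na(ann)]
  if (!is.na(x$concentration)) {
    ann <- c(ann, concentration = sprintf("%g uM", x$concentration))
  }
  if (length(ann)) {
    cat(" ", paste(names(ann), ann, sep = "=", collapse = ", "), "\n")
  }
  gt <- attr(x, "ground_truth")
  if (!is.null(gt)) {
    cat(sprintf("  synthetic: preset %s, %d beats, event %s\n",
                gt$preset_name, length(gt$onsets), gt$event$type))
  }
  invisible(x)
}

#' @export
plot.cw_trace <- function(x, ..., xlim = NULL) {
  graphics::plot(x$time, x$signal, type = "l", xlab = "time (s)",
                 ylab = "fluorescence (a.u.)",
                 main = paste("well", x$well_id), xlim = xlim, ...)
  invisible(x)
}
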