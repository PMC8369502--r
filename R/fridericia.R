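#' Fridericia rate correction
#'
#' Rate-corrects a repolarization duration by the cube root of the preceding
#' inter-beat interval, the QTcF convention carried over to optically recorded
#' pulse-width durations: `PWDcF = PWD / IBI^(1/3)` with the IBI in seconds.
#' At an inter-beat interval of exactly 1 s the correction is the identity.
#'
#' @param pwd Duration(s) in milliseconds.
#' @param ibi Preceding inter-beat interval(s) in seconds; must be positive.
#' @return Corrected duration(s) in milliseconds.
#' @seealso [fridericia_uncorrect()] for the inverse mapping.
#' @examples
#' fridericia_correct(300, 1)      # 300: identity at 1 s
#' fridericia_correct(200, 0.5)    # ~252 ms
#' @export
fridericia_correct <- function(pwd, ibi) {
  if (any(!is.finite(ibi)) || any(ibi <= 0)) {
    stop("'ibi' must be positive and finite (seconds)", call. = FALSE)
  }
  pwd / ibi^(1 / 3)
}

#' Invert the Fridericia correction
#'
#' Maps a rate-corrected duration back to the raw duration expected at a given
#' inter-beat interval: `PWD = PWDcF * IBI^(1/3)`. Used by the simulator to
#' turn corrected duration targets (which is how plate readers report them)
#' into the uncorrected durations that must actually be generated at the
#' preset's spontaneous rate.
#'
#' @param pwd_corrected Corrected duration(s) in milliseconds.
#' @param ibi Inter-beat interval(s) in seconds; must be positive.
#' @return Uncorrected duration(s) in milliseconds.
#' @examples
#' # round trip
#' fridericia_correct(fridericia_uncorrect(156.1, 60 / 237), 60 / 237)
#' @export
fridericia_uncorrect <- function(pwd_corrected, ibi) {
  if (any(!is.finite(ibi)) || any(ibi <= 0)) {
    stop("'ibi' must be positive and finite (seconds)", call. = FALSE)
  }
  pwd_corrected * ibi^(1 / 3)
}
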