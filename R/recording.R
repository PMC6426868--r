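# Channel-recording container: per source-detector-pair amplitude time
# series with triggers, channel metadata and artifact annotations.

#' Construct a channel recording
#'
#' @param amplitudes Channels x time numeric matrix. For raw recordings these
#'   are strictly positive intensities; after optical-density conversion the
#'   stored signal is \eqn{-\Delta\log} amplitude and may be negative
#'   (`signal` = "od").
#' @param times_s Strictly increasing base sample times (s). Individual
#'   channels may carry a small `time_offset_s` (sequential source scanning)
#'   in the `channels` table; `times_s + offset` is each channel's own grid.
#' @param channels Tibble with `source`, `detector`, `sds_mm` and optional
#'   `time_offset_s`, `wavelength_nm` per row of `amplitudes`.
#' @param triggers Tibble with `onset_s`, `condition`.
#' @param annotations Tibble with `onset_s`, `duration_s`, `label`
#'   (movement / crying / noise); synthetic stand-in for video coding.
#' @param signal `"intensity"` or `"od"`.
#' @param meta Free-form metadata list (frame interval, seed, truth, ...).
#' @return A `dot_recording`.
#' @export
new_recording <- function(amplitudes, times_s, channels,
                          triggers = tibble::tibble(onset_s = numeric(), condition = character()),
                          annotations = tibble::tibble(onset_s = numeric(), duration_s = numeric(), label = character()),
                          signal = c("intensity", "od"),
                          meta = list()) {
  signal <- match.arg(signal)
  amplitudes <- as.matrix(amplitudes)
  channels <- tibble::as_tibble(channels)
  if (!"time_offset_s" %in% names(channels)) channels$time_offset_s <- 0
  rec <- structure(
    list(amplitudes = amplitudes, times_s = as.numeric(times_s),
         channels = channels, triggers = tibble::as_tibble(triggers),
         annotations = tibble::as_tibble(annotations),
         signal = signal, meta = meta),
    class = "dot_recording"
  )
  validate_recording(rec)
}

#' Validate a recording's invariants
#'
#' Checks positivity of raw intensities, strictly increasing times, channel
#' table alignment, and that every trigger falls within the recorded span.
#' @param rec A `dot_recording`.
#' @return The recording, invisibly-checked (errors on violation).
#' @export
validate_recording <- function(rec) {
  if (nrow(rec$channels) != nrow(rec$amplitudes)) {
    rlang::abort("channel table and amplitude rows disagree")
  }
  if (length(rec$times_s) != ncol(rec$amplitudes)) {
    rlang::abort("times_s length and amplitude columns disagree")
  }
  if (any(diff(rec$times_s) <= 0)) rlang::abort("times_s must be strictly increasing")
  if (rec$signal == "intensity" && any(rec$amplitudes <= 0)) {
    rlang::abort("raw amplitudes must be strictly positive before log transforms")
  }
  span <- range(rec$times_s)
  if (nrow(rec$triggers) > 0 &&
      (any(rec$triggers$onset_s < span[1]) || any(rec$triggers$onset_s > span[2]))) {
    rlang::abort("every trigger must lie within the recording span")
  }
  rec
}

#' @export
print.dot_recording <- function(x, ...) {
  cat("<dot_recording> ", nrow(x$amplitudes), " channels x ",
      ncol(x$amplitudes), " samples (", x$signal, "), ",
      nrow(x$triggers), " triggers, ", nrow(x$annotations), " annotations\n",
      sep = "")
  invisible(x)
}

#' Long-format view of a recording
#' @param x A `dot_recording`.
#' @param ... Unused.
#' @return Tibble `channel`, `source`, `detector`, `sds_mm`, `time_s`, `value`.
#' @method as_tibble dot_recording
#' @export
as_tibble.dot_recording <- function(x, ...) {
  nch <- nrow(x$amplitudes)
  nt <- ncol(x$amplitudes)
  tibble::tibble(
    channel = rep(seq_len(nch), times = nt),
    source = rep(x$channels$source, times = nt),
    detector = rep(x$channels$detector, times = nt),
    sds_mm = rep(x$channels$sds_mm, times = nt),
    time_s = rep(x$times_s, each = nch) +
      rep(x$channels$time_offset_s, times = nt),
    value = as.vector(x$amplitudes)
  )
}

#' Convert raw intensities to optical-density change
#'
#' Per channel, \eqn{-\log(A / \bar A)} where \eqn{\bar A} is the channel's
#' mean amplitude; this is the Rytov-convention signal whose first-order
#' relation to absorption changes the sensitivity matrix encodes.
#' @param rec A `dot_recording` with `signal = "intensity"`.
#' @return The recording with `signal = "od"`.
#' @export
optical_density <- function(rec) {
  if (rec$signal != "intensity") return(rec)
  m <- rowMeans(rec$amplitudes)
  rec$amplitudes <- -log(rec$amplitudes / m)
  rec$signal <- "od"
  rec
}
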