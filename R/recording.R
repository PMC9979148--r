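# Multichannel neural recording container shared by the synthetic
# generators and the analysis chain.

#' Construct a multichannel recording
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param sample_rate Sampling rate, Hz.
#' @param metadata Data frame with one row per channel: `channel_id`,
#'   `hemisphere` (`"L"` or `"R"`), `contact_order` (integer position along
#'   the electrode shank).  A default layout is built if omitted.
#' @param events Stimulus event (onset) times in seconds, within the record.
#' @param condition Free-form condition label.
#' @return A `flicker_recording`.
#' @export
new_recording <- function(data, sample_rate, metadata = NULL, events = numeric(0),
                          condition = "unknown") {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  n_ch <- nrow(data)
  if (is.null(metadata)) {
    metadata <- data.frame(
      channel_id = paste0("ch", seq_len(n_ch)),
      hemisphere = rep(c("L", "R"), length.out = n_ch),
      contact_order = seq_len(n_ch))
  }
  req <- c("channel_id", "hemisphere", "contact_order")
  if (!all(req %in% names(metadata)))
    stopf("metadata must have columns %s", paste(req, collapse = ", "))
  if (nrow(metadata) != n_ch)
    stopf("metadata has %d rows but data has %d channels", nrow(metadata), n_ch)
  dur <- ncol(data) / sample_rate
  if (length(events) && (min(events) < 0 || max(events) > dur))
    stopf("event times must lie within the record span [0, %g] s", dur)
  structure(list(data = data, sample_rate = sample_rate, metadata = metadata,
                 events = as.numeric(events), condition = condition),
            class = "flicker_recording")
}

#' @export
print.flicker_recording <- function(x, ...) {
  cat(sprintf("<flicker_recording> %d channels x %.2f s @ %g Hz (%s), %d events\n",
              nrow(x$data), ncol(x$data) / x$sample_rate, x$sample_rate,
              x$condition, length(x$events)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param x A `flicker_recording`.
#' @export
recording_duration <- function(x) ncol(x$data) / x$sample_rate
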