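# Delimited-text readers/writers for every container (the same formats the
# analysis functions consume) and a minimal 16-bit PCM WAV writer/reader
# for audio waveform export.

#' Write / read a recording as delimited text
#'
#' The trace goes to `<path>` (tab-delimited, one row per sample, one
#' column per channel, `time_s` first) and the channel metadata to
#' `<path>.meta` (channel_id, hemisphere, contact_order).  Events and the
#' condition label travel in comment headers.
#'
#' @param recording A `flicker_recording`.
#' @param path Output file.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "flicker_recording"))
  con <- file(path, "w")
  writeLines(c(sprintf("# sample_rate\t%.10g", recording$sample_rate),
               sprintf("# condition\t%s", recording$condition),
               sprintf("# events\t%s",
                       paste(sprintf("%.10g", recording$events),
                             collapse = ","))), con)
  df <- as.data.frame(t(recording$data))
  names(df) <- recording$metadata$channel_id
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  write.table(recording$metadata, paste0(path, ".meta"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 3)
  get <- function(key) sub(paste0("^# ", key, "\t"), "",
                           hdr[startsWith(hdr, paste0("# ", key))])
  sample_rate <- as.numeric(get("sample_rate"))
  condition <- get("condition")
  ev <- get("events")
  events <- if (nzchar(ev)) as.numeric(strsplit(ev, ",")[[1]]) else numeric(0)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE)
  md <- read.table(paste0(path, ".meta"), header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "integer"))
  new_recording(t(as.matrix(df)), sample_rate, md, events, condition)
}

#' Write / read a spike train (one spike time per line)
#'
#' @param spikes A `spike_train` or numeric vector of times.
#' @param path Output file.
#' @export
write_spike_train <- function(spikes, path) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  writeLines(sprintf("%.10g", times), path)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path, unit_id = "unit1") {
  times <- as.numeric(readLines(path))
  if (is.unsorted(times)) stopf("spike times in %s are not sorted", path)
  structure(list(times = times, unit_id = unit_id), class = "spike_train")
}

#' Write / read a trajectory (t, x, y delimited, tracker-export style)
#'
#' @param traj A `flicker_trajectory`.
#' @param path Output file.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "flicker_trajectory"))
  con <- file(path, "w")
  writeLines(c(sprintf("# arena\t%.10g\t%.10g", traj$arena[1], traj$arena[2]),
               sprintf("# center_zone\t%s",
                       paste(sprintf("%.10g", traj$center_zone),
                             collapse = "\t"))), con)
  write.table(traj$data, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  hdr <- readLines(path, n = 2)
  arena <- as.numeric(strsplit(sub("^# arena\t", "", hdr[1]), "\t")[[1]])
  zone <- as.numeric(strsplit(sub("^# center_zone\t", "", hdr[2]), "\t")[[1]])
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  new_trajectory(df, arena, zone)
}

#' Write a PSD result as delimited text (freq, channel, power_db)
#'
#' @param psd A `psd_result`.
#' @param path Output file.
#' @export
write_psd <- function(psd, path) {
  stopifnot(inherits(psd, "psd_result"))
  long <- data.frame(freq = rep(psd$freq, ncol(psd$power_db)),
                     channel = rep(psd$channel_id, each = length(psd$freq)),
                     power_db = as.vector(psd$power_db))
  write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export waveform timing as delimited text
#'
#' `write_cycle_log` writes the per-cycle on/off/duty table;
#' `write_events` writes onset times as an event file (`time_s`, `label`);
#' `write_control_signal` writes the sampled signal (`time_s`, `value`).
#'
#' @param w A `stim_waveform`.
#' @param path Output file.
#' @export
write_cycle_log <- function(w, path) {
  stopifnot(inherits(w, "stim_waveform"))
  write.table(w$cycle_log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cycle_log
#' @param label Event label used for every onset.
#' @export
write_events <- function(w, path, label = "onset") {
  stopifnot(inherits(w, "stim_waveform"))
  write.table(data.frame(time_s = w$onsets, label = label), path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cycle_log
#' @export
write_control_signal <- function(w, path) {
  stopifnot(inherits(w, "stim_waveform"))
  t <- (seq_along(w$samples) - 1) / w$sample_rate
  write.table(data.frame(time_s = t, value = w$samples), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a waveform as 16-bit PCM WAV
#'
#' Minimal RIFF/WAVE writer: mono, 16-bit signed little-endian, sample rate
#' from the waveform.  Samples are clipped to `[-1, 1]` and scaled to
#' 32767.
#'
#' @param w A `stim_waveform` (or numeric vector in `[-1, 1]` with
#'   `sample_rate`).
#' @param path Output `.wav` file.
#' @param sample_rate Required for bare numeric input.
#' @export
write_wav <- function(w, path, sample_rate = NULL) {
  if (inherits(w, "stim_waveform")) {
    x <- w$samples
    sample_rate <- w$sample_rate
  } else x <- w
  if (is.null(sample_rate)) stopf("`sample_rate` required")
  pcm <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stopf("not a RIFF/WAVE file")
  repeat {
    id <- readChar(con, 4)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      sample_rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 2, 2, endian = "little"))
      if (fmt[1] != 1L) stopf("only PCM supported")
    } else if (id == "data") {
      pcm <- readBin(con, "integer", size / 2, 2, signed = TRUE,
                     endian = "little")
      return(list(samples = pcm / 32767, sample_rate = sample_rate))
    } else seek(con, size, origin = "current")
  }
}
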