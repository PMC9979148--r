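# Experiment task schedules and the blinded condition-assignment protocol.
# A schedule is a data frame of non-overlapping trials (condition label,
# modality, frequency or "random", start time, duration) with interleaved
# rest periods.

new_task_schedule <- function(trials, task_type) {
  if (nrow(trials) > 1 &&
      any(trials$start_s[-1] < (trials$start_s + trials$duration_s)[-nrow(trials)] - 1e-9))
    stopf("trials overlap")
  structure(list(trials = trials, task_type = task_type,
                 total_duration = if (nrow(trials))
                   max(trials$start_s + trials$duration_s) else 0),
            class = "task_schedule")
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("<task_schedule> %s: %d trials, %.0f s total\n", x$task_type,
              nrow(x$trials), x$total_duration))
  invisible(x)
}

trial_row <- function(condition, modality, freq, start, duration) {
  data.frame(condition = condition, modality = modality,
             freq = as.character(freq), start_s = start,
             duration_s = duration)
}

lay_out_trials <- function(conds, trial_duration, rest, t0 = 0) {
  n <- nrow(conds)
  conds$start_s <- t0 + (seq_len(n) - 1) * (trial_duration + rest)
  conds$duration_s <- trial_duration
  conds
}

#' Classical flicker task schedule
#'
#' Every combination of the given modalities with the four classical
#' conditions -- 5.5 Hz (theta-like), 40 Hz (gamma-like), 80 Hz, and random
#' nonperiodic flicker -- in seeded shuffled order with rest periods
#' between trials.
#'
#' @param modalities Subset of `c("visual", "audiovisual", "auditory")`.
#' @param trial_duration Trial length, s.
#' @param rest Rest between trials, s.
#' @param order_seed Integer seed for the trial order shuffle.
#' @param freqs Conditions; the default is the classical set, where
#'   `"random"` denotes aperiodic flicker.
#' @return A `task_schedule`.
#' @export
build_classical_task <- function(modalities = c("visual", "audiovisual",
                                                "auditory"),
                                 trial_duration = 120, rest = 30,
                                 order_seed = 1,
                                 freqs = c("5.5", "40", "80", "random")) {
  modalities <- unique(modalities)
  if (!length(modalities)) stopf("at least one modality required")
  bad <- setdiff(modalities, c("visual", "audiovisual", "auditory"))
  if (length(bad)) stopf("unknown modalities: %s", paste(bad, collapse = ", "))
  grid <- expand.grid(modality = modalities, freq = freqs,
                      stringsAsFactors = FALSE)
  grid <- with_seed(order_seed, grid[sample(nrow(grid)), , drop = FALSE])
  trials <- trial_row(paste(grid$freq, grid$modality, sep = "_"),
                      grid$modality, grid$freq, 0, 0)
  new_task_schedule(lay_out_trials(trials, trial_duration, rest),
                    "classical")
}

#' Flicker frequency task schedule
#'
#' One trial per frequency (up to 26 distinct frequencies) at a single
#' modality.
#'
#' @param freqs Distinct flicker frequencies, Hz; `1 <= length(freqs) <= 26`.
#' @param modality Stimulation modality.
#' @inheritParams build_classical_task
#' @export
build_frequency_task <- function(freqs, modality = "audiovisual",
                                 trial_duration = 60, rest = 30) {
  if (!length(freqs)) stopf("at least one frequency required")
  if (length(freqs) > 26) stopf("at most 26 frequencies supported")
  if (anyDuplicated(freqs)) stopf("frequencies must be distinct")
  trials <- trial_row(paste0(freqs, "Hz_", modality), modality, freqs, 0, 0)
  new_task_schedule(lay_out_trials(trials, trial_duration, rest), "frequency")
}

#' Flicker duration task schedule
#'
#' A single uninterrupted exposure to one modality and frequency for
#' `total_minutes` minutes (e.g. the 1-h mouse protocol).
#'
#' @param modality Stimulation modality.
#' @param freq Flicker frequency in Hz, or `"random"`.
#' @param total_minutes Exposure length in minutes.
#' @export
build_duration_task <- function(modality = "audiovisual", freq = 40,
                                total_minutes = 60) {
  check_scalar(total_minutes, "total_minutes", lower = 0, strict_lower = TRUE)
  trials <- trial_row(paste0(freq, "Hz_", modality), modality, freq, 0,
                      total_minutes * 60)
  new_task_schedule(trials, "duration")
}

#' Single-pulse evoked-potential task schedule
#'
#' `n_pulses` single 12.5-ms pulses per modality at a fixed inter-pulse
#' interval.
#'
#' @param modalities Modalities receiving pulses.
#' @param n_pulses Pulses per modality.
#' @param inter_pulse_interval Onset-to-onset interval, s.
#' @param width_ms Pulse width, ms.
#' @export
build_pulse_task <- function(modalities = c("visual", "audiovisual",
                                            "auditory"),
                             n_pulses = 10, inter_pulse_interval = 2,
                             width_ms = 12.5) {
  if (n_pulses < 0) stopf("n_pulses must be non-negative")
  if (n_pulses == 0)
    return(new_task_schedule(trial_row(character(0), character(0),
                                       character(0), numeric(0), numeric(0)),
                             "pulse"))
  check_scalar(inter_pulse_interval, "inter_pulse_interval", lower = 0,
               strict_lower = TRUE)
  rows <- list()
  t0 <- 0
  for (m in modalities) {
    for (i in seq_len(n_pulses)) {
      rows[[length(rows) + 1L]] <-
        trial_row(paste0("pulse_", m), m, "pulse", t0, width_ms / 1000)
      t0 <- t0 + inter_pulse_interval
    }
  }
  new_task_schedule(do.call(rbind, rows), "pulse")
}

#' Read a blinding assignment table
#'
#' Two-column delimited file mapping opaque subject identifiers to
#' stimulation conditions, prepared by a non-blinded third party.
#'
#' @param path File with columns `subject_id`, `condition` (tab- or
#'   comma-delimited, header required).
#' @return A `blinding_table` data frame.
#' @export
read_blinding_table <- function(path) {
  sep <- if (grepl(",", readLines(path, n = 1))) "," else "\t"
  tab <- read.table(path, header = TRUE, sep = sep,
                    colClasses = "character", strip.white = TRUE)
  if (!all(c("subject_id", "condition") %in% names(tab)))
    stopf("blinding table needs columns subject_id, condition")
  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup))
    stopf("duplicate subject ids in blinding table: %s",
          paste(unique(dup), collapse = ", "))
  class(tab) <- c("blinding_table", "data.frame")
  tab
}

#' Salted condition code
#'
#' MD5 of `salt:condition`, used wherever a session log must not reveal
#' the condition in plain text.
#'
#' @param condition Condition label.
#' @param salt Salt string shared by one study.
#' @export
condition_code <- function(condition, salt = "flickerkit") {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste0(salt, ":", condition), f)
  unname(tools::md5sum(f))
}

#' Resolve a subject's blinded session schedule
#'
#' Looks up the subject in the blinding table and returns the full session:
#' a fixed test sequence (identical for every condition, so the
#' experimenter-observable part carries no condition information), a pause
#' during which the experimenter leaves, then the condition-specific
#' stimulation block.  The condition is returned only as a salted code;
#' `reveal = TRUE` additionally returns the plain label for the unblinding
#' step.
#'
#' @param table A `blinding_table`.
#' @param subject_id Identifier entered by the blinded experimenter.
#' @param stimulation_minutes Length of the stimulation block, minutes.
#' @param test_seq_duration Test-sequence length, s (1-Hz light+tone
#'   pulses).
#' @param pause Pause between test sequence and stimulation, s.
#' @param salt Salt for the condition code.
#' @param reveal Include the plain condition label (unblinded use only).
#' @return List: `subject_id`, `condition_code`, `schedule`
#'   (`task_schedule` whose stimulation trial carries the coded label), and
#'   `condition` if revealed.
#' @export
resolve_blinded_condition <- function(table, subject_id,
                                      stimulation_minutes = 60,
                                      test_seq_duration = 2, pause = 30,
                                      salt = "flickerkit", reveal = FALSE) {
  stopifnot(inherits(table, "blinding_table"))
  hit <- match(subject_id, table$subject_id)
  if (is.na(hit))
    stopf("subject id '%s' not found in the blinding table", subject_id)
  condition <- table$condition[hit]
  code <- condition_code(condition, salt)

  test_seq <- trial_row("test_sequence", "audiovisual", "1", 0,
                        test_seq_duration)
  stim_start <- test_seq_duration + pause
  stim <- trial_row(paste0("stim_", code), "audiovisual", "coded",
                    stim_start, stimulation_minutes * 60)
  out <- list(subject_id = subject_id, condition_code = code,
              schedule = new_task_schedule(rbind(test_seq, stim), "blinded"))
  if (reveal) out$condition <- condition
  out
}

#' Write / read a task schedule as a delimited event file
#'
#' Schedules serialize to tab-delimited text (columns `condition`,
#' `modality`, `freq`, `start_s`, `duration_s`) and reload losslessly.
#'
#' @param schedule A `task_schedule`.
#' @param path Output file.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "task_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# task_type\t", schedule$task_type), con)
  write.table(schedule$trials, con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  first <- readLines(path, n = 1)
  task_type <- sub("^# task_type\t", "", first)
  trials <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                       colClasses = c("character", "character", "character",
                                      "numeric", "numeric"))
  new_task_schedule(trials, task_type)
}
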