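# Entrainment statistics: the channel- and subject-level modulation
# criteria, detection latency, stimulation-vs-control contrasts, spike
# phase locking, and the occluded-condition artifact check.

#' Channel-level modulation criterion
#'
#' A channel is modulated when its power at the stimulation frequency is at
#' least `sd_threshold` standard deviations above the mean power in the
#' neighboring frequency bands (defaults: 31-39 and 41-49 Hz around a 40-Hz
#' stimulus).  The z-score is computed on dB power by default, matching the
#' units modulation results are reported in (`scale = "linear"` z-scores
#' raw power instead).  The comparison is inclusive (`z >= threshold`).
#'
#' @param psd A `psd_result` whose grid covers `stim_freq` and both
#'   neighbor bands.
#' @param stim_freq Stimulation frequency, Hz; the nearest grid bin is used.
#' @param neighbor_bands List of two `c(lo, hi)` bands (Hz, inclusive).
#' @param sd_threshold Modulation threshold in SD units.
#' @param scale `"db"` or `"linear"` power scale for the z-score.
#' @return Data frame with one row per channel: `channel_id`, `hemisphere`,
#'   `power_at_stim`, `neighbor_mean`, `neighbor_sd`, `z_score`,
#'   `modulated`.
#' @export
channel_modulation <- function(psd, stim_freq = 40,
                               neighbor_bands = list(c(31, 39), c(41, 49)),
                               sd_threshold = 3, scale = c("db", "linear")) {
  stopifnot(inherits(psd, "psd_result"))
  scale <- match.arg(scale)
  f <- psd$freq
  if (stim_freq < min(f) || stim_freq > max(f))
    stopf("PSD grid does not cover stim_freq = %g Hz", stim_freq)
  stim_bin <- which.min(abs(f - stim_freq))
  nb <- unlist(lapply(neighbor_bands, function(b)
    which(f >= b[1] & f <= b[2])))
  nb <- setdiff(unique(nb), stim_bin)
  if (length(nb) < 2)
    stopf("neighbor bands contain %d bins; >= 2 required for an SD", length(nb))
  pw <- if (scale == "db") psd$power_db else 10^(psd$power_db / 10)
  p_stim <- pw[stim_bin, ]
  mu <- apply(pw[nb, , drop = FALSE], 2, mean)
  sdev <- apply(pw[nb, , drop = FALSE], 2, sd)
  z <- (p_stim - mu) / sdev
  data.frame(channel_id = psd$channel_id,
             hemisphere = psd$hemisphere,
             power_at_stim = p_stim, neighbor_mean = mu, neighbor_sd = sdev,
             z_score = z, modulated = z >= sd_threshold,
             row.names = NULL)
}

#' Subject-level modulation criterion
#'
#' A subject is modulated when at least `min_channels` channels are
#' modulated and the modulated set spans hemispheres.  The default
#' `hemisphere_rule = "each"` requires at least one modulated channel in
#' each hemisphere (the criterion achieved in practice); `"either"` accepts
#' a modulated channel in either hemisphere, a permissive reading under
#' which the hemisphere clause is implied by `min_channels >= 1`.
#'
#' @param channels Data frame from [channel_modulation()] (columns
#'   `hemisphere`, `modulated`).
#' @param min_channels Minimum number of modulated channels.
#' @param hemisphere_rule `"each"` or `"either"`.
#' @return A `modulation_report`: the per-channel table, per-hemisphere
#'   modulated counts, and the subject decision.
#' @export
subject_modulation <- function(channels, min_channels = 3,
                               hemisphere_rule = c("each", "either")) {
  hemisphere_rule <- match.arg(hemisphere_rule)
  if (any(is.na(channels$hemisphere)))
    stopf("every channel needs a hemisphere label")
  n_mod <- sum(channels$modulated)
  counts <- c(L = sum(channels$modulated & channels$hemisphere == "L"),
              R = sum(channels$modulated & channels$hemisphere == "R"))
  hemi_ok <- if (hemisphere_rule == "each") all(counts >= 1)
             else any(counts >= 1)
  structure(list(channels = channels, hemisphere_counts = counts,
                 n_modulated = n_mod,
                 subject_modulated = (n_mod >= min_channels) && hemi_ok,
                 hemisphere_rule = hemisphere_rule,
                 min_channels = min_channels),
            class = "modulation_report")
}

#' @export
print.modulation_report <- function(x, ...) {
  cat(sprintf("<modulation_report> %d/%d channels modulated (L: %d, R: %d); subject %s (rule: >=%d channels, %s hemisphere)\n",
              x$n_modulated, nrow(x$channels), x$hemisphere_counts["L"],
              x$hemisphere_counts["R"],
              if (x$subject_modulated) "MODULATED" else "not modulated",
              x$min_channels, x$hemisphere_rule))
  invisible(x)
}

#' Detection latency of subject-level modulation
#'
#' Applies the channel + subject criteria to growing windows anchored at
#' stimulus onset, in `window_step`-second increments, and returns the
#' smallest window length at which the subject criterion is met (`NA` if it
#' never is within the record).  With robust responses the criterion is
#' typically met within seconds, well inside the 10-s bound observed in
#' practice.
#'
#' @param recording A `flicker_recording`.
#' @param onset Stimulus onset time (s); defaults to the first recorded
#'   event.
#' @param window_step Window growth increment, s.
#' @param stim_freq Stimulation frequency, Hz.
#' @param sd_threshold,min_channels,hemisphere_rule Criterion parameters,
#'   see [channel_modulation()] and [subject_modulation()].
#' @param neighbor_bands Neighbor bands for the channel criterion.
#' @param time_bandwidth,n_tapers Multitaper parameters.
#' @param max_window Largest window tried, s (default: to end of record).
#' @return Latency in seconds (multiple of `window_step`) or `NA_real_`.
#' @export
detection_latency <- function(recording, onset = NULL, window_step = 1,
                              stim_freq = 40,
                              neighbor_bands = list(c(31, 39), c(41, 49)),
                              sd_threshold = 3, min_channels = 3,
                              hemisphere_rule = "each",
                              time_bandwidth = 3, n_tapers = 5,
                              max_window = NULL) {
  stopifnot(inherits(recording, "flicker_recording"))
  if (is.null(onset)) {
    if (!length(recording$events)) stopf("no onset given and no events recorded")
    onset <- recording$events[1]
  }
  dur <- recording_duration(recording)
  if (onset < 0 || onset >= dur) stopf("onset outside the record")
  if (is.null(max_window)) max_window <- dur - onset
  sr <- recording$sample_rate
  lo <- min(vapply(neighbor_bands, min, numeric(1)))
  hi <- max(vapply(neighbor_bands, max, numeric(1)))
  band <- c(min(lo, stim_freq) - 1, max(hi, stim_freq) + 1)
  for (w in seq(window_step, max_window + 1e-9, by = window_step)) {
    i0 <- round(onset * sr) + 1L
    i1 <- min(round((onset + w) * sr), ncol(recording$data))
    seg <- new_recording(recording$data[, i0:i1, drop = FALSE], sr,
                         recording$metadata)
    psd <- multitaper_psd(seg, band = band, time_bandwidth = time_bandwidth,
                          n_tapers = n_tapers)
    ch <- channel_modulation(psd, stim_freq, neighbor_bands, sd_threshold)
    rep <- subject_modulation(ch, min_channels, hemisphere_rule)
    if (rep$subject_modulated) return(w)
  }
  NA_real_
}

#' Stimulation-vs-control contrast of power at the stimulus frequency
#'
#' Paired t test, Wilcoxon signed-rank test, and Cohen's d on per-trial
#' power at the stimulation frequency, with medians and quartiles per
#' condition.  Cohen's d is the paired form, `mean(stim - control) /
#' sd(stim - control)`.
#'
#' @param stim_power,control_power Numeric vectors of per-trial power (dB)
#'   at the stimulation frequency; equal lengths (paired trials).
#' @return List: `paired_t_p`, `wilcoxon_p`, `cohens_d`, and per-condition
#'   `medians` and `quartiles`.
#' @export
condition_contrast <- function(stim_power, control_power) {
  n <- length(stim_power)
  if (n != length(control_power)) stopf("paired design needs equal trial counts")
  if (n < 2) stopf("need at least 2 trials")
  d <- stim_power - control_power
  q <- function(x) quantile(x, c(0.25, 0.75), names = FALSE)
  if (sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    # degenerate pairing: identical sets give no evidence of a shift; a
    # constant non-zero difference is an unambiguous one
    zero_d <- all(abs(d) < 1e-12 * max(1, abs(stim_power), abs(control_power)))
    t_p <- if (zero_d) 1 else 0
    cohens_d <- if (zero_d) 0 else sign(mean(d)) * Inf
    wt_p <- if (zero_d) 1 else
      suppressWarnings(wilcox.test(stim_power, control_power, paired = TRUE,
                                   exact = FALSE)$p.value)
    return(list(paired_t_p = t_p, wilcoxon_p = unname(wt_p),
                cohens_d = cohens_d,
                medians = c(stim = median(stim_power),
                            control = median(control_power)),
                quartiles = list(stim = q(stim_power),
                                 control = q(control_power)),
                n = n))
  }
  cohens_d <- mean(d) / sd(d)
  tt <- t.test(stim_power, control_power, paired = TRUE)
  wt <- suppressWarnings(wilcox.test(stim_power, control_power, paired = TRUE,
                                     exact = FALSE))
  list(paired_t_p = unname(tt$p.value), wilcoxon_p = unname(wt$p.value),
       cohens_d = cohens_d,
       medians = c(stim = median(stim_power), control = median(control_power)),
       quartiles = list(stim = q(stim_power), control = q(control_power)),
       n = n)
}

#' Spike phase locking to the stimulus
#'
#' Assigns each spike a phase `2 * pi * frac((t - preceding onset) *
#' stim_freq)` relative to the nearest preceding stimulus onset and
#' summarizes with the mean resultant vector: `vector_strength` (1 = all
#' spikes at one phase, 0 = uniform), `preferred_phase`, and the Rayleigh
#' uniformity test p-value.
#'
#' @param spike_times Sorted spike times, s.
#' @param stim_freq Stimulation frequency, Hz.
#' @param stim_onsets Stimulus onset times, s; spikes before the first
#'   onset are dropped.
#' @param min_spikes Below this count the result is flagged insufficient.
#' @return A `spike_phase_stats` list: `vector_strength`,
#'   `preferred_phase`, `n_spikes`, `uniformity_p`, `insufficient_data`.
#' @export
spike_phase_locking <- function(spike_times, stim_freq, stim_onsets = 0,
                                min_spikes = 10) {
  if (is.unsorted(spike_times, strictly = FALSE))
    stopf("spike times must be sorted")
  keep <- spike_times >= min(stim_onsets)
  st <- spike_times[keep]
  n <- length(st)
  if (n < min_spikes) {
    return(structure(list(vector_strength = NA_real_,
                          preferred_phase = NA_real_, n_spikes = n,
                          uniformity_p = NA_real_, insufficient_data = TRUE),
                     class = "spike_phase_stats"))
  }
  prec <- stim_onsets[findInterval(st, stim_onsets)]
  phase <- 2 * pi * (((st - prec) * stim_freq) %% 1)
  C <- mean(cos(phase)); S <- mean(sin(phase))
  R <- sqrt(C^2 + S^2)
  # Rayleigh test with Zar's finite-n correction
  Rn <- n * R
  z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  structure(list(vector_strength = R, preferred_phase = atan2(S, C),
                 n_spikes = n, uniformity_p = min(max(p, 0), 1),
                 insufficient_data = FALSE),
            class = "spike_phase_stats")
}

#' @export
print.spike_phase_stats <- function(x, ...) {
  if (x$insufficient_data)
    cat(sprintf("<spike_phase_stats> insufficient data (%d spikes)\n", x$n_spikes))
  else
    cat(sprintf("<spike_phase_stats> VS = %.3f, phase = %.2f rad, n = %d, Rayleigh p = %.3g\n",
                x$vector_strength, x$preferred_phase, x$n_spikes, x$uniformity_p))
  invisible(x)
}

#' Occluded-condition artifact check
#'
#' The occluded condition (subject shielded from the stimuli by an eye mask
#' and earplugs) should show no modulation; any channel meeting the
#' modulation criterion while the stimulator runs indicates an electrical
#' artifact rather than a sensory response.
#'
#' @param psd_occluded `psd_result` from the occluded-condition recording.
#' @inheritParams channel_modulation
#' @return `TRUE` if an artifact is suspected (any modulated channel).
#' @export
occluded_check <- function(psd_occluded, stim_freq = 40,
                           neighbor_bands = list(c(31, 39), c(41, 49)),
                           sd_threshold = 3) {
  ch <- channel_modulation(psd_occluded, stim_freq, neighbor_bands,
                           sd_threshold)
  any(ch$modulated)
}
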