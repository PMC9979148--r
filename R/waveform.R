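# Stimulus waveform synthesis: periodic square waves, carrier-modulated
# click trains, randomized aperiodic flicker, and single pulses, all with
# per-cycle timing logs so generated stimuli can be verified sample by
# sample.

new_stim_waveform <- function(samples, sample_rate, onsets, cycle_log,
                              amplitude, modality = "visual",
                              condition = "periodic", carrier_freq = NA_real_) {
  structure(
    list(samples = samples, sample_rate = sample_rate, onsets = onsets,
         cycle_log = cycle_log, amplitude = amplitude, modality = modality,
         condition = condition, carrier_freq = carrier_freq),
    class = "stim_waveform")
}

#' @export
print.stim_waveform <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate
  cat(sprintf("<stim_waveform> %s/%s: %.3f s @ %g Hz, %d cycles, amplitude %g\n",
              x$modality, x$condition, dur, x$sample_rate,
              nrow(x$cycle_log), x$amplitude))
  if (!is.na(x$carrier_freq))
    cat(sprintf("  carrier: %g Hz\n", x$carrier_freq))
  invisible(x)
}

# A sample at time t is on iff its fractional cycle phase lies in [0, duty),
# so the first sample of every cycle is on.  Phase is rounded to guard the
# boundary against floating-point error.
square_envelope <- function(n, flicker_freq, duty, sample_rate) {
  phase <- round(((seq_len(n) - 1) * flicker_freq / sample_rate) %% 1, 9)
  phase < duty | (duty >= 1)
}

periodic_cycle_log <- function(flicker_freq, duty, duration) {
  n_full <- floor(duration * flicker_freq + 1e-9)
  period_ms <- 1000 / flicker_freq
  data.frame(cycle = seq_len(n_full),
             on_ms = rep(duty * period_ms, n_full),
             off_ms = rep((1 - duty) * period_ms, n_full),
             duty = rep(duty, n_full))
}

periodic_onsets <- function(flicker_freq, duration) {
  k <- ceiling(duration * flicker_freq - 1e-9)
  (seq_len(k) - 1) / flicker_freq
}

check_waveform_args <- function(flicker_freq, duty, duration, sample_rate,
                                amplitude) {
  check_scalar(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  check_scalar(flicker_freq, "flicker_freq", lower = 0, upper = sample_rate / 2,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(duty, "duty", lower = 0, upper = 1)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(amplitude, "amplitude", lower = 0, upper = 1)
}

#' Periodic square-wave flicker control signal
#'
#' Generates the canonical visual flicker drive: a square wave at
#' `flicker_freq` where each cycle is high (`= amplitude`) for
#' `duty / flicker_freq` seconds from the cycle start and zero otherwise.
#' The 40 Hz, 50%-duty default configuration has 12.5-ms on-phases, the
#' standard gamma-flicker stimulus.  `duty = 1` yields the constant-on
#' (non-flickering light) control.
#'
#' @param flicker_freq Flicker frequency in Hz; must be below Nyquist.
#' @param duty On fraction of each cycle, in `[0, 1]`.
#' @param duration Signal duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param amplitude Peak level, unitless in `[0, 1]` (hardware voltage and
#'   lux calibration are outside the scope of the control signal).
#' @return A `stim_waveform`: sampled signal, onset times of each on-phase,
#'   and a per-cycle log of on/off durations and duty.
#' @examples
#' w <- square_wave(40, 0.5, duration = 1, sample_rate = 40000)
#' measure_waveform(w)$fundamental_freq
#' @export
square_wave <- function(flicker_freq, duty, duration, sample_rate,
                        amplitude = 1) {
  check_waveform_args(flicker_freq, duty, duration, sample_rate, amplitude)
  n <- round(duration * sample_rate)
  samples <- amplitude * as.numeric(
    square_envelope(n, flicker_freq, duty, sample_rate))
  cond <- if (duty >= 1) "constant" else "periodic"
  new_stim_waveform(samples, sample_rate,
                    onsets = periodic_onsets(flicker_freq, duration),
                    cycle_log = periodic_cycle_log(flicker_freq, duty, duration),
                    amplitude = amplitude, modality = "visual",
                    condition = cond)
}

#' Carrier-modulated audio flicker (click train)
#'
#' A pure sinusoid tone gated by a square-wave envelope: the audio analogue
#' of visual flicker.  Audiovisual stimulation conventionally uses a
#' 50%-duty envelope; audio-only stimulation uses a 4% duty so each cycle is
#' a short click, matching auditory steady-state-response click trains.
#' Carrier tones are species-adjusted (10 kHz for mice, 7-8 kHz for humans).
#'
#' @param carrier_freq Tone frequency in Hz; must exceed `flicker_freq` and
#'   lie below Nyquist.
#' @inheritParams square_wave
#' @return A `stim_waveform` with `modality = "audio"`.
#' @examples
#' w <- modulated_tone(8000, 40, 0.04, duration = 1, sample_rate = 44100)
#' round(measure_waveform(w)$duty, 2)
#' @export
modulated_tone <- function(carrier_freq, flicker_freq, duty, duration,
                           sample_rate, amplitude = 1) {
  check_waveform_args(flicker_freq, duty, duration, sample_rate, amplitude)
  check_scalar(carrier_freq, "carrier_freq", lower = flicker_freq,
               upper = sample_rate / 2, strict_lower = TRUE,
               strict_upper = TRUE)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  env <- as.numeric(square_envelope(n, flicker_freq, duty, sample_rate))
  samples <- amplitude * sin(2 * pi * carrier_freq * t) * env
  new_stim_waveform(samples, sample_rate,
                    onsets = periodic_onsets(flicker_freq, duration),
                    cycle_log = periodic_cycle_log(flicker_freq, duty, duration),
                    amplitude = amplitude, modality = "audio",
                    condition = if (duty >= 1) "constant" else "periodic",
                    carrier_freq = carrier_freq)
}

#' Randomized aperiodic flicker
#'
#' The aperiodicity control condition: every on-phase lasts exactly `on_ms`
#' (matching the periodic condition's light-on time) while off-intervals are
#' drawn i.i.d. uniform on `off_range` milliseconds.  With the default
#' 12.5-ms on-phase and off-intervals on \[0, 25\] ms, per-cycle duty varies
#' between 33% and 100% and the mean cycle rate matches 40 Hz.
#'
#' @param on_ms On-phase duration in ms (held fixed across cycles).
#' @param off_range Length-2 numeric, min and max off-interval in ms.
#' @param seed Integer seed; equal seeds give bit-identical output.
#' @inheritParams square_wave
#' @return A `stim_waveform` whose `cycle_log` records every complete cycle.
#' @examples
#' w <- random_flicker(12.5, c(0, 25), duration = 5, sample_rate = 40000,
#'                     seed = 1)
#' range(w$cycle_log$duty)
#' @export
random_flicker <- function(on_ms, off_range = c(0, 25), duration, sample_rate,
                           amplitude = 1, seed = NULL) {
  check_scalar(on_ms, "on_ms", lower = 0, strict_lower = TRUE)
  if (length(off_range) != 2L || !is.numeric(off_range))
    stopf("`off_range` must be numeric of length 2")
  if (off_range[2] < off_range[1] || off_range[1] < 0)
    stopf("`off_range` must satisfy 0 <= min <= max")
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  check_scalar(amplitude, "amplitude", lower = 0, upper = 1)

  n <- round(duration * sample_rate)
  on_n <- max(1L, round(on_ms * sample_rate / 1000))
  mean_cycle_n <- on_n + mean(off_range) * sample_rate / 1000
  with_seed(seed, {
    offs_ms <- numeric(0)
    total <- 0L
    while (total < n) {
      batch <- ceiling((n - total) / max(mean_cycle_n, 1) * 1.2) + 16L
      new_off <- runif(batch, off_range[1], off_range[2])
      offs_ms <- c(offs_ms, new_off)
      total <- total + sum(on_n + round(new_off * sample_rate / 1000))
    }
    off_n <- as.integer(round(offs_ms * sample_rate / 1000))
    cyc_n <- on_n + off_n
    ends <- cumsum(cyc_n)
    n_full <- sum(ends <= n)
    n_started <- sum(c(0, ends) < n)   # cycles whose onset falls in record

    lens <- as.vector(rbind(rep(on_n, n_started),
                            off_n[seq_len(n_started)]))
    samples <- rep(rep(c(amplitude, 0), n_started), lens)
    length(samples) <- n               # truncate partial final cycle
    samples[is.na(samples)] <- 0

    onsets <- c(0, ends[seq_len(n_started - 1)]) / sample_rate
    full <- seq_len(n_full)
    cycle_log <- data.frame(
      cycle = full,
      on_ms = rep(on_n / sample_rate * 1000, n_full),
      off_ms = off_n[full] / sample_rate * 1000,
      duty = on_n / cyc_n[full])
    new_stim_waveform(samples, sample_rate, onsets = onsets,
                      cycle_log = cycle_log, amplitude = amplitude,
                      modality = "visual", condition = "random")
  })
}

#' Single sensory pulse
#'
#' One isolated on-phase of `width_ms` milliseconds starting at t = 0, used
#' for evoked-potential tasks.  Audio modalities carry the sinusoid carrier
#' tone within the pulse.
#'
#' @param modality One of `"visual"`, `"audio"`, `"audiovisual"`.
#' @param width_ms Pulse width in ms (default 12.5, the on-time of one
#'   40 Hz / 50%-duty cycle).
#' @param carrier_freq Carrier tone in Hz, required for audio modalities.
#' @param duration Total record length in seconds (zero after the pulse).
#' @inheritParams square_wave
#' @export
single_pulse <- function(modality = c("visual", "audio", "audiovisual"),
                         width_ms = 12.5, sample_rate, carrier_freq = NULL,
                         amplitude = 1, duration = 1) {
  modality <- match.arg(modality)
  check_scalar(width_ms, "width_ms", lower = 0, strict_lower = TRUE)
  check_scalar(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  check_scalar(duration, "duration", lower = width_ms / 1000)
  if (modality != "visual") {
    if (is.null(carrier_freq))
      stopf("`carrier_freq` is required for audio modalities")
    check_scalar(carrier_freq, "carrier_freq", lower = 0,
                 upper = sample_rate / 2, strict_lower = TRUE,
                 strict_upper = TRUE)
  }
  n <- round(duration * sample_rate)
  w_n <- round(width_ms / 1000 * sample_rate)
  env <- c(rep(1, w_n), rep(0, n - w_n))
  samples <- if (modality == "visual") amplitude * env else {
    t <- (seq_len(n) - 1) / sample_rate
    amplitude * sin(2 * pi * carrier_freq * t) * env
  }
  cycle_log <- data.frame(cycle = 1L, on_ms = w_n / sample_rate * 1000,
                          off_ms = (n - w_n) / sample_rate * 1000,
                          duty = w_n / n)
  new_stim_waveform(samples, sample_rate, onsets = 0, cycle_log = cycle_log,
                    amplitude = amplitude, modality = modality,
                    condition = "single_pulse",
                    carrier_freq = if (modality == "visual") NA_real_
                                   else carrier_freq)
}

#' Offset an audio waveform against a visual waveform
#'
#' Shifts the audio stream by `delay_ms` relative to the visual stream
#' (positive = audio lags), quantized to the nearest sample.  Auditory and
#' visual transmission times through their pathways differ, so a
#' deliberate inter-modal delay can align arrival at cortex.
#'
#' @param visual,audio `stim_waveform` objects with equal sample rates.
#' @param delay_ms Signed delay in milliseconds.
#' @return List with elements `visual` and `audio`; the audio waveform's
#'   samples and onsets are shifted, and the attribute
#'   `"delay_quantization_ms"` records the (requested - applied) remainder.
#' @export
pair_with_delay <- function(visual, audio, delay_ms) {
  stopifnot(inherits(visual, "stim_waveform"), inherits(audio, "stim_waveform"))
  if (visual$sample_rate != audio$sample_rate)
    stopf("sample rates differ (%g vs %g Hz)", visual$sample_rate,
          audio$sample_rate)
  check_scalar(delay_ms, "delay_ms")
  sr <- audio$sample_rate
  shift_n <- round(delay_ms / 1000 * sr)
  applied_ms <- shift_n / sr * 1000
  x <- audio$samples
  n <- length(x)
  shifted <- if (shift_n >= 0) c(rep(0, shift_n), x)[seq_len(n)]
             else c(x[-seq_len(-shift_n)], rep(0, -shift_n))
  out <- audio
  out$samples <- shifted
  out$onsets <- audio$onsets + applied_ms / 1000
  attr(out, "delay_quantization_ms") <- delay_ms - applied_ms
  attr(out, "applied_delay_ms") <- applied_ms
  list(visual = visual, audio = out)
}

#' Dominant spectral frequency of a sampled signal
#'
#' Location of the largest magnitude bin of the mean-removed discrete
#' Fourier transform, in Hz.  Resolution is `sample_rate / length(x)`.
#'
#' @param x Numeric signal.
#' @param sample_rate Sampling rate in Hz.
#' @export
dominant_frequency <- function(x, sample_rate) {
  n <- length(x)
  if (n < 4) stopf("signal too short")
  p <- Mod(fft(x - mean(x)))^2
  half <- 2:floor(n / 2)
  (which.max(p[half]) + 0L) * sample_rate / n
}

# Close FALSE runs shorter than `gap` samples inside a logical mask.
close_gaps <- function(mask, gap) {
  r <- rle(mask)
  inner <- seq_along(r$values)
  short_off <- !r$values & r$lengths <= gap &
    inner > 1 & inner < length(r$values)
  r$values[short_off] <- TRUE
  inverse.rle(r)
}

#' Measure frequency and duty cycle of a waveform
#'
#' The software analogue of putting the stimulus on an oscilloscope: the
#' verification path for every generator.  The on/off envelope is recovered
#' by thresholding the rectified signal at half its maximum (for
#' carrier-modulated audio, sub-carrier-period dips are first closed), the
#' fundamental is taken from inter-onset intervals (falling back to the
#' spectral peak of the rectified signal when fewer than two onsets exist),
#' and duty is the per-cycle fraction of time above threshold, averaged over
#' complete cycles.
#'
#' @param w A `stim_waveform`, or any numeric signal via `as_waveform`
#'   semantics (`w$samples`, `w$sample_rate`).
#' @return List with `fundamental_freq` (Hz, `NA` and `fundamental_defined =
#'   FALSE` for constant or single-event signals), `duty` (fraction),
#'   `onset_phase_ms` (time of the first detected onset), and `n_cycles`.
#' @export
measure_waveform <- function(w) {
  x <- w$samples
  sr <- w$sample_rate
  n <- length(x)
  if (n == 0) stopf("empty waveform")
  A <- max(abs(x))
  if (A == 0)
    return(list(fundamental_freq = NA_real_, fundamental_defined = FALSE,
                duty = 0, onset_phase_ms = NA_real_, n_cycles = 0L))
  mask <- abs(x) >= A / 2
  if (all(mask))
    return(list(fundamental_freq = NA_real_, fundamental_defined = FALSE,
                duty = 1, onset_phase_ms = 0, n_cycles = 0L))

  f_raw <- dominant_frequency(x, sr)
  f_env <- dominant_frequency(abs(x), sr)
  if (is.finite(f_env) && f_env > 0 && f_raw > 3 * f_env) {
    # carrier-modulated: close the sub-carrier-period dips of |sin|
    mask <- close_gaps(mask, ceiling(sr / f_raw) + 1L)
  }

  onset_idx <- which(diff(c(FALSE, mask)) == 1L)
  if (length(onset_idx) >= 2) {
    period_n <- median(diff(onset_idx))
    fundamental <- sr / period_n
    defined <- TRUE
    # duty over complete cycles (onset to next onset)
    k <- length(onset_idx) - 1L
    duties <- vapply(seq_len(k), function(i) {
      a <- onset_idx[i]; b <- onset_idx[i + 1L] - 1L
      on_run <- which(mask[a:b])
      (max(on_run) - min(on_run) + 1L) / (b - a + 1L)
    }, numeric(1))
    duty <- mean(duties)
    n_cycles <- k
  } else {
    fundamental <- NA_real_
    defined <- FALSE
    on_run <- which(mask)
    duty <- (max(on_run) - min(on_run) + 1L) / n
    n_cycles <- length(onset_idx)
  }
  list(fundamental_freq = fundamental, fundamental_defined = defined,
       duty = duty,
       onset_phase_ms = (onset_idx[1] - 1L) / sr * 1000,
       n_cycles = n_cycles)
}

#' Stimulus specification
#'
#' Bundles the parameters of one stimulation condition.  Default sample
#' rates are 40 kHz for visual control signals and 44.1 kHz for audio (so a
#' 10-kHz mouse carrier sits below Nyquist and waveforms export directly to
#' WAV).
#'
#' @param modality `"visual"`, `"audio"`, or `"audiovisual"`.
#' @param flicker_freq Flicker frequency, Hz.
#' @param duty On fraction per cycle.
#' @param carrier_freq Carrier tone in Hz (audio modalities).
#' @param amplitude Unitless peak in `[0, 1]`.
#' @param duration Seconds.
#' @param sample_rate Hz; modality-dependent default.
#' @param condition `"periodic"`, `"random"`, `"constant"`, `"single_pulse"`.
#' @param audio_visual_delay Signed audio lag, ms (audiovisual only).
#' @param seed Integer, required for `condition = "random"`.
#' @export
waveform_spec <- function(modality = c("visual", "audio", "audiovisual"),
                          flicker_freq = 40, duty = 0.5, carrier_freq = NULL,
                          amplitude = 1, duration = 1,
                          sample_rate = NULL,
                          condition = c("periodic", "random", "constant",
                                        "single_pulse"),
                          audio_visual_delay = 0, seed = NULL) {
  modality <- match.arg(modality)
  condition <- match.arg(condition)
  if (is.null(sample_rate))
    sample_rate <- if (modality == "visual") 40000 else 44100
  check_waveform_args(flicker_freq, duty, duration, sample_rate, amplitude)
  if (modality != "visual" && is.null(carrier_freq))
    stopf("`carrier_freq` is required for audio modalities")
  if (!is.null(carrier_freq))
    check_scalar(carrier_freq, "carrier_freq", lower = 0,
                 upper = sample_rate / 2, strict_upper = TRUE)
  if (condition == "random" && is.null(seed))
    stopf("`seed` is required for the random condition")
  structure(list(modality = modality, flicker_freq = flicker_freq,
                 duty = duty, carrier_freq = carrier_freq,
                 amplitude = amplitude, duration = duration,
                 sample_rate = sample_rate, condition = condition,
                 audio_visual_delay = audio_visual_delay, seed = seed),
            class = "waveform_spec")
}

#' Generate the waveform(s) for a stimulus specification
#'
#' @param spec A [waveform_spec()].
#' @param off_range Off-interval range (ms) for the random condition.
#' @return A `stim_waveform`, or for `modality = "audiovisual"` a list with
#'   `visual` and `audio` streams offset by `audio_visual_delay`.
#' @export
generate_waveform <- function(spec, off_range = c(0, 25)) {
  stopifnot(inherits(spec, "waveform_spec"))
  gen_one <- function(modality) {
    switch(spec$condition,
      periodic = ,
      constant = {
        duty <- if (spec$condition == "constant") 1 else spec$duty
        if (modality == "visual")
          square_wave(spec$flicker_freq, duty, spec$duration,
                      spec$sample_rate, spec$amplitude)
        else
          modulated_tone(spec$carrier_freq, spec$flicker_freq, duty,
                         spec$duration, spec$sample_rate, spec$amplitude)
      },
      random = random_flicker(spec$duty / spec$flicker_freq * 1000, off_range,
                              spec$duration, spec$sample_rate,
                              spec$amplitude, seed = spec$seed),
      single_pulse = single_pulse(modality, 12.5, spec$sample_rate,
                                  spec$carrier_freq, spec$amplitude,
                                  spec$duration))
  }
  if (spec$modality == "audiovisual") {
    pair_with_delay(gen_one("visual"), gen_one("audio"),
                    spec$audio_visual_delay)
  } else gen_one(spec$modality)
}
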