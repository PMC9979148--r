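# Seeded synthetic data with the statistical structure the analysis chain
# assumes: 1/f-background multichannel EEG/LFP with an additive steady-state
# response phase-locked to stimulus onset, cosine-modulated Poisson spike
# trains, and open-field trajectories with stationary bouts.

# Colored noise by spectral shaping of white Gaussian noise: amplitude
# spectrum proportional to f^(-exponent/2) so power goes as 1/f^exponent.
colored_noise <- function(n, sample_rate, exponent = 1, sd_target = 1) {
  z <- fft(rnorm(n))
  f <- (seq_len(n) - 1) * sample_rate / n
  f[f > sample_rate / 2] <- sample_rate - f[f > sample_rate / 2]  # mirror
  g <- c(0, f[-1]^(-exponent / 2))
  x <- Re(fft(z * g, inverse = TRUE)) / n
  x / sd(x) * sd_target
}

#' Synthetic multichannel EEG/LFP with a steady-state evoked response
#'
#' Each channel is 1/f-background colored noise (unit SD) plus, from
#' `stim_onset` on, a sinusoid at `stim_freq` with phase zero at onset --
#' the minimal surrogate for a steady-state response phase-locked to the
#' stimulus.  Defaults emulate a 32-channel scalp EEG acquisition at
#' 2048 Hz with 16 channels per hemisphere.
#'
#' @param n_channels Number of channels.
#' @param hemisphere_map Character vector of `"L"`/`"R"` per channel;
#'   default first half `"L"`, second half `"R"`.
#' @param sample_rate Hz.
#' @param duration Record length, s.
#' @param stim_freq Stimulation frequency, Hz.
#' @param stim_onset Stimulation start, s (must precede `duration`).
#' @param response_amplitude Response amplitude in background-SD units;
#'   scalar or one value per channel.
#' @param background_exponent Spectral exponent of the 1/f background.
#' @param harmonics Optional integer vector of extra harmonics (e.g.
#'   `c(2, 3)`) added at 1/harmonic relative amplitude.
#' @param seed Integer seed; equal seeds give identical recordings.
#' @return A `flicker_recording` with `events = stim_onset`.
#' @export
gen_ssep_recording <- function(n_channels = 32, hemisphere_map = NULL,
                               sample_rate = 2048, duration = 60,
                               stim_freq = 40, stim_onset = 20,
                               response_amplitude = 1,
                               background_exponent = 1, harmonics = NULL,
                               seed = NULL) {
  if (stim_onset >= duration) stopf("stim_onset must precede duration")
  if (length(response_amplitude) == 1L)
    response_amplitude <- rep(response_amplitude, n_channels)
  if (length(response_amplitude) != n_channels)
    stopf("response_amplitude must have 1 or n_channels values")
  if (is.null(hemisphere_map))
    hemisphere_map <- rep(c("L", "R"), each = ceiling(n_channels / 2))[
      seq_len(n_channels)]
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  on <- t >= stim_onset
  resp <- sin(2 * pi * stim_freq * (t - stim_onset)) * on
  if (!is.null(harmonics))
    for (h in harmonics)
      resp <- resp + sin(2 * pi * h * stim_freq * (t - stim_onset)) * on / h
  with_seed(seed, {
    data <- matrix(0, n_channels, n)
    for (ch in seq_len(n_channels))
      data[ch, ] <- colored_noise(n, sample_rate, background_exponent) +
        response_amplitude[ch] * resp
    new_recording(data, sample_rate,
                  metadata = data.frame(
                    channel_id = paste0("ch", seq_len(n_channels)),
                    hemisphere = hemisphere_map,
                    contact_order = stats::ave(seq_len(n_channels),
                                               hemisphere_map,
                                               FUN = seq_along)),
                  events = stim_onset, condition = sprintf("%gHz", stim_freq))
  })
}

#' Calibrate the response amplitude to a target channel z-score
#'
#' Finds by bisection the `response_amplitude` at which the mean
#' channel-criterion z-score over `window` seconds of stimulation reaches
#' `target_z`, averaged over a few seeds.  Used to construct recordings
#' whose detectability is controlled in criterion units rather than raw
#' amplitude.
#'
#' @param target_z Target mean per-channel z-score.
#' @param window Analysis window length, s.
#' @param stim_freq,sample_rate,background_exponent As in
#'   [gen_ssep_recording()].
#' @param seeds Seeds averaged over during calibration.
#' @param neighbor_bands,time_bandwidth,n_tapers Criterion/estimator
#'   parameters.
#' @return Calibrated amplitude (background-SD units).
#' @export
calibrate_response_amplitude <- function(target_z = 6, window = 10,
                                         stim_freq = 40, sample_rate = 2048,
                                         background_exponent = 1,
                                         seeds = 1:3,
                                         neighbor_bands = list(c(31, 39),
                                                               c(41, 49)),
                                         time_bandwidth = 3, n_tapers = 5) {
  mean_z <- function(amp) {
    zs <- vapply(seeds, function(s) {
      rec <- gen_ssep_recording(n_channels = 4, sample_rate = sample_rate,
                                duration = window, stim_freq = stim_freq,
                                stim_onset = 0, response_amplitude = amp,
                                background_exponent = background_exponent,
                                seed = s)
      psd <- multitaper_psd(rec, band = c(2, 100),
                            time_bandwidth = time_bandwidth,
                            n_tapers = n_tapers)
      mean(channel_modulation(psd, stim_freq, neighbor_bands)$z_score)
    }, numeric(1))
    mean(zs)
  }
  lo <- 1e-4; hi <- 1
  while (mean_z(hi) < target_z && hi < 100) hi <- hi * 4
  for (i in 1:12) {
    mid <- sqrt(lo * hi)
    if (mean_z(mid) < target_z) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Cosine-modulated (phase-locked) Poisson spike train
#'
#' Inhomogeneous Poisson process with rate `lambda(t) = base_rate * (1 +
#' mod_depth * cos(2 * pi * stim_freq * t - preferred_phase))`, simulated
#' by thinning (exact for bounded rates).  At full modulation depth the
#' asymptotic vector strength is exactly 1/2.
#'
#' @param base_rate Mean firing rate, Hz.
#' @param mod_depth Modulation depth m in `[0, 1]`.
#' @param stim_freq Stimulation frequency, Hz.
#' @param preferred_phase Preferred firing phase, radians.
#' @param duration Train length, s.
#' @param seed Integer seed.
#' @param unit_id Label carried with the train.
#' @return A `spike_train`: sorted `times` (s) and `unit_id`.
#' @export
gen_phase_locked_spikes <- function(base_rate, mod_depth = 0, stim_freq = 40,
                                    preferred_phase = 0, duration = 60,
                                    seed = NULL, unit_id = "unit1") {
  check_scalar(base_rate, "base_rate", lower = 0, strict_lower = TRUE)
  check_scalar(mod_depth, "mod_depth", lower = 0, upper = 1)
  lambda_max <- base_rate * (1 + mod_depth)
  with_seed(seed, {
    n_cand <- rpois(1, lambda_max * duration)
    cand <- sort(runif(n_cand, 0, duration))
    lam <- base_rate * (1 + mod_depth * cos(2 * pi * stim_freq * cand -
                                            preferred_phase))
    keep <- runif(n_cand) < lam / lambda_max
    structure(list(times = cand[keep], unit_id = unit_id),
              class = "spike_train")
  })
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes over %.1f s\n", x$unit_id,
              length(x$times), if (length(x$times)) max(x$times) else 0))
  invisible(x)
}

#' Synthetic open-field trajectory with stationary bouts
#'
#' Frames at `frame_rate` over `duration` seconds inside a rectangular
#' arena.  `"move"` bouts are a reflected Gaussian random walk with steps
#' large relative to the inactivity bounding box; `"still"` bouts hold
#' position with jitter confined to a region far smaller than 0.01% of the
#' arena area.  A still bout spanning `[a, a + d]` includes both boundary
#' frames, so its frame span is exactly `d` seconds.
#'
#' @param arena `c(width, height)` in cm.
#' @param duration Session length, s.
#' @param frame_rate Frames per second.
#' @param bout_plan Data frame with columns `state` (`"move"`/`"still"`)
#'   and `duration` (s), applied from t = 0; time past the plan is
#'   `"move"`.
#' @param move_step SD of the per-frame random-walk step, cm.
#' @param still_jitter Half-width of the stationary jitter square, cm.
#' @param seed Integer seed.
#' @return A `flicker_trajectory`: data frame `(t, x, y)` plus arena
#'   geometry and the default center zone (central rectangle of 50% linear
#'   dimensions).
#' @export
gen_trajectory <- function(arena = c(30, 30), duration = 60, frame_rate = 30,
                           bout_plan = NULL, move_step = NULL,
                           still_jitter = NULL, seed = NULL) {
  if (any(arena <= 0)) stopf("arena dimensions must be positive")
  if (is.null(move_step)) move_step <- 0.05 * min(arena)
  if (is.null(still_jitter)) still_jitter <- 0.001 * min(arena)
  n <- round(duration * frame_rate) + 1L
  t <- (seq_len(n) - 1L) / frame_rate
  state <- rep("move", n)
  if (!is.null(bout_plan)) {
    if (sum(bout_plan$duration) > duration + 1e-9)
      stopf("bout plan exceeds duration")
    ends <- cumsum(bout_plan$duration)
    starts <- c(0, ends[-length(ends)])
    for (i in seq_len(nrow(bout_plan)))
      if (bout_plan$state[i] == "still")
        state[t >= starts[i] - 1e-9 & t <= ends[i] + 1e-9] <- "still"
  }
  with_seed(seed, {
    x <- numeric(n); y <- numeric(n)
    x[1] <- arena[1] / 2; y[1] <- arena[2] / 2
    anchor <- c(x[1], y[1])
    for (i in seq_len(n)[-1]) {
      if (state[i] == "still") {
        if (state[i - 1] != "still") {
          # step of fixed length move_step into the stop position so the
          # preceding move frame always lies outside the stationary
          # bounding region
          theta <- runif(1, 0, 2 * pi)
          anchor <- c(x[i - 1] + move_step * cos(theta),
                      y[i - 1] + move_step * sin(theta))
          anchor <- pmin(pmax(anchor, still_jitter * 2),
                         arena - still_jitter * 2)
        }
        x[i] <- anchor[1] + runif(1, -still_jitter, still_jitter)
        y[i] <- anchor[2] + runif(1, -still_jitter, still_jitter)
      } else {
        x[i] <- x[i - 1] + rnorm(1, 0, move_step)
        y[i] <- y[i - 1] + rnorm(1, 0, move_step)
      }
      # reflect at walls
      x[i] <- abs(x[i]); if (x[i] > arena[1]) x[i] <- 2 * arena[1] - x[i]
      y[i] <- abs(y[i]); if (y[i] > arena[2]) y[i] <- 2 * arena[2] - y[i]
    }
    new_trajectory(data.frame(t = t, x = x, y = y), arena)
  })
}

#' Construct a trajectory object
#'
#' @param data Data frame with columns `t`, `x`, `y` (s, cm, cm), strictly
#'   increasing `t`, positions inside the arena.
#' @param arena `c(width, height)` cm.
#' @param center_zone `c(x0, y0, x1, y1)` cm; default the central rectangle
#'   of 50% linear dimensions.
#' @export
new_trajectory <- function(data, arena, center_zone = NULL) {
  stopifnot(all(c("t", "x", "y") %in% names(data)))
  if (is.unsorted(data$t, strictly = TRUE)) stopf("t must be strictly increasing")
  if (any(data$x < -1e-9 | data$x > arena[1] + 1e-9 |
          data$y < -1e-9 | data$y > arena[2] + 1e-9))
    stopf("positions outside the arena")
  if (is.null(center_zone))
    center_zone <- c(arena[1] / 4, arena[2] / 4,
                     3 * arena[1] / 4, 3 * arena[2] / 4)
  structure(list(data = data, arena = as.numeric(arena),
                 center_zone = as.numeric(center_zone)),
            class = "flicker_trajectory")
}

#' @export
print.flicker_trajectory <- function(x, ...) {
  cat(sprintf("<flicker_trajectory> %d frames over %.1f s in %g x %g cm arena\n",
              nrow(x$data), diff(range(x$data$t)), x$arena[1], x$arena[2]))
  invisible(x)
}
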