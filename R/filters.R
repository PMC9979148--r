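# Preprocessing chain: FIR band-pass, anti-aliased downsampling, Laplacian
# re-referencing, per-segment baseline correction, and a driver that
# enforces their order.

# Linear-phase FIR applied with exact group-delay compensation via FFT
# convolution.  For a symmetric (Hamming-windowed) FIR this is zero-phase
# and O(n log n), which matters for the long kernels a 1-Hz low edge needs.
fir_apply_zerophase <- function(x, h) {
  n <- length(x)
  m <- length(h)
  delay <- (m - 1L) %/% 2L
  nfft <- stats::nextn(n + m - 1L, 2)
  y <- Re(fft(fft(c(x, rep(0, nfft - n))) *
              fft(c(h, rep(0, nfft - m))), inverse = TRUE)) / nfft
  y[(delay + 1L):(delay + n)]
}

fir_bandpass_kernel <- function(low, high, sample_rate,
                                transition_frac = 0.25) {
  # Hamming main-lobe transition width ~3.3 / N (normalized); keep the
  # transition band no wider than transition_frac of the low cutoff.
  trans_hz <- transition_frac * low
  ntaps <- ceiling(3.3 * sample_rate / trans_hz)
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  ntaps <- max(ntaps, 31L)
  signal::fir1(ntaps - 1L, c(low, high) / (sample_rate / 2), type = "pass")
}

#' Band-pass filter a recording
#'
#' Hamming-windowed FIR band-pass applied with zero phase (group-delay
#' compensated linear-phase kernel).  The filter order is chosen so the
#' transition band is at most 25% of the low cutoff, giving >= 50 dB
#' stop-band attenuation one octave outside the band and < 1 dB pass-band
#' ripple.  Typical bands in the analysis chain: 1-100 Hz for scalp EEG PSD,
#' 1-300 Hz for LFP, 2-300 Hz for intracranial LFP, 300-6000 Hz for spikes.
#'
#' @param recording A `flicker_recording` (or numeric vector plus
#'   `sample_rate`).
#' @param low,high Band edges in Hz, `0 < low < high < Nyquist`.
#' @param sample_rate Required when `recording` is a bare numeric vector.
#' @return Filtered object of the same type.
#' @export
bandpass <- function(recording, low, high, sample_rate = NULL) {
  if (inherits(recording, "flicker_recording")) sample_rate <- recording$sample_rate
  check_scalar(low, "low", lower = 0, strict_lower = TRUE)
  if (!(low < high && high < sample_rate / 2))
    stopf("band [%g, %g] must satisfy 0 < low < high < Nyquist (%g Hz)",
          low, high, sample_rate / 2)
  h <- fir_bandpass_kernel(low, high, sample_rate)
  if (inherits(recording, "flicker_recording")) {
    recording$data <- t(apply(recording$data, 1, fir_apply_zerophase, h = h))
    recording
  } else fir_apply_zerophase(recording, h)
}

#' Downsample a recording with anti-alias filtering
#'
#' For integer decimation factors an FIR anti-alias low-pass (cutoff at 80%
#' of the new Nyquist) is applied before index decimation; awkward ratios
#' fall back to polyphase resampling.  Raw wide-band acquisitions (e.g.
#' 20 kHz probe data) are brought to 2 kHz before LFP analysis this way.
#'
#' @inheritParams bandpass
#' @param target_rate New sampling rate in Hz, below the current rate.
#' @export
downsample <- function(recording, target_rate, sample_rate = NULL) {
  is_rec <- inherits(recording, "flicker_recording")
  if (is_rec) sample_rate <- recording$sample_rate
  if (target_rate > sample_rate) stopf("target_rate exceeds current rate")
  if (target_rate == sample_rate) return(recording)
  one <- function(x) {
    if (abs(sample_rate / target_rate - round(sample_rate / target_rate)) < 1e-9) {
      q <- round(sample_rate / target_rate)
      cutoff <- 0.8 * (target_rate / 2)
      trans <- 0.2 * (target_rate / 2)
      ntaps <- ceiling(3.3 * sample_rate / trans)
      if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
      h <- signal::fir1(ntaps - 1L, cutoff / (sample_rate / 2), type = "low")
      fir_apply_zerophase(x, h)[seq(1L, length(x), by = q)]
    } else {
      p_q <- c(round(target_rate), round(sample_rate))
      g <- gcd_int(p_q[1], p_q[2])
      as.numeric(signal::resample(x, p_q[1] / g, p_q[2] / g))
    }
  }
  if (is_rec) {
    recording$data <- t(apply(recording$data, 1, one))
    recording$sample_rate <- target_rate
    recording
  } else one(recording)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Laplacian re-reference along the electrode shank
#'
#' Subtracts the average of spatially adjacent contacts from each channel:
#' interior contact i becomes `x_i - (x_{i-1} + x_{i+1}) / 2`, which
#' localizes the signal by removing common-mode and linearly varying
#' (volume-conducted) components.  Contacts are ordered by `contact_order`
#' within each hemisphere group (one shank per hemisphere); edge contacts
#' get the one-sided difference `x_0 - x_1` and are flagged in the metadata
#' column `laplacian_edge`.
#'
#' @param recording A `flicker_recording` with >= 3 contacts per shank.
#' @export
laplacian_rereference <- function(recording) {
  stopifnot(inherits(recording, "flicker_recording"))
  md <- recording$metadata
  out <- recording$data
  edge <- logical(nrow(md))
  for (h in unique(md$hemisphere)) {
    idx <- which(md$hemisphere == h)
    idx <- idx[order(md$contact_order[idx])]
    k <- length(idx)
    if (k < 3) stopf("hemisphere %s has %d contacts; >= 3 required", h, k)
    x <- recording$data[idx, , drop = FALSE]
    y <- x
    y[1, ] <- x[1, ] - x[2, ]
    y[k, ] <- x[k, ] - x[k - 1, ]
    for (i in 2:(k - 1)) y[i, ] <- x[i, ] - (x[i - 1, ] + x[i + 1, ]) / 2
    out[idx, ] <- y
    edge[idx[c(1, k)]] <- TRUE
  }
  recording$data <- out
  recording$metadata$laplacian_edge <- edge
  recording
}

#' Per-segment baseline (DC) correction
#'
#' Splits each channel into consecutive non-overlapping segments of
#' `segment_length` seconds (default 12, the record-segment length used for
#' intracranial analysis) and subtracts the segment mean; a final partial
#' segment is corrected by its own mean.
#'
#' @inheritParams bandpass
#' @param segment_length Segment length in seconds.
#' @export
baseline_correct <- function(recording, segment_length = 12,
                             sample_rate = NULL) {
  is_rec <- inherits(recording, "flicker_recording")
  if (is_rec) sample_rate <- recording$sample_rate
  check_scalar(segment_length, "segment_length", lower = 0, strict_lower = TRUE)
  seg_n <- round(segment_length * sample_rate)
  one <- function(x) {
    n <- length(x)
    grp <- (seq_len(n) - 1L) %/% seg_n
    x - ave(x, grp)
  }
  if (is_rec) {
    recording$data <- t(apply(recording$data, 1, one))
    recording
  } else one(recording)
}

#' Run the standard preprocessing chain
#'
#' Enforces the canonical order: downsample, band-pass, optional Laplacian
#' re-reference, per-segment baseline correction.
#'
#' @param recording A `flicker_recording`.
#' @param downsample_to Target rate in Hz, or `NULL` to keep the native rate.
#' @param band Band-pass edges in Hz, or `NULL` to skip.
#' @param laplacian Apply Laplacian re-referencing.
#' @param baseline_segment Baseline-correction segment length (s), or `NULL`.
#' @export
preprocess <- function(recording, downsample_to = NULL, band = c(1, 100),
                       laplacian = FALSE, baseline_segment = 12) {
  stopifnot(inherits(recording, "flicker_recording"))
  if (!is.null(downsample_to) && downsample_to < recording$sample_rate)
    recording <- downsample(recording, downsample_to)
  if (!is.null(band)) recording <- bandpass(recording, band[1], band[2])
  if (laplacian) recording <- laplacian_rereference(recording)
  if (!is.null(baseline_segment))
    recording <- baseline_correct(recording, baseline_segment)
  recording
}
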