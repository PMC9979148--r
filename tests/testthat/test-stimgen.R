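# Stimulus generators and the oscilloscope-style measurement path.

test_that("periodic square wave geometry and measurement round-trip", {
  w <- square_wave(40, 0.5, 1, 40000)
  expect_length(w$samples, 40000)
  # 12.5-ms on-phase = 500 samples per cycle at 40 kHz
  expect_equal(sum(w$samples[1:1000] > 0.5), 500)
  expect_equal(w$onsets[1], 0)
  expect_equal(diff(w$onsets)[1], 1 / 40)
  expect_true(all(w$cycle_log$on_ms == 12.5))
  m <- measure_waveform(w)
  expect_equal(m$fundamental_freq, 40)
  expect_equal(m$duty, 0.5)

  # narrow duty: on-phase = duty * period = 1 ms = 40 samples per cycle
  w2 <- square_wave(40, 0.04, 1, 40000)
  per_cycle <- matrix(w2$samples > 0.5, nrow = 1000)
  expect_true(all(colSums(per_cycle) == 40))

  # constant-on control
  wc <- square_wave(40, 1, 1, 40000)
  expect_true(all(wc$samples == 1))
  mc <- measure_waveform(wc)
  expect_equal(mc$duty, 1)
  expect_false(mc$fundamental_defined)

  # theta-like frequency recovered
  expect_equal(measure_waveform(square_wave(5.5, 0.5, 2, 40000))$fundamental_freq,
               5.5, tolerance = 1e-3)

  # round trip across the parameter grid, one-sample-period tolerance
  for (f in c(5.5, 20, 40, 80)) {
    for (duty in c(0.2, 0.5, 0.8)) {
      m <- measure_waveform(square_wave(f, duty, 2, 40000))
      expect_equal(m$fundamental_freq, f, tolerance = f^2 / 40000 + 1e-9)
      expect_equal(m$duty, duty, tolerance = f / 40000 * 2)
    }
  }
})

test_that("duty conservation: on-sample fraction equals duty over full cycles", {
  for (duty in c(0.1, 0.25, 0.5, 0.9)) {
    w <- square_wave(40, duty, 1, 40000)   # exactly 40 full cycles
    expect_equal(mean(w$samples > 0.5), duty, tolerance = 1 / 40)
  }
})

test_that("carrier-modulated tone: spectrum, envelope, and click duty", {
  w <- modulated_tone(8000, 40, 0.5, 1, 44100)
  expect_equal(dominant_frequency(w$samples, 44100), 8000)
  # rectified-envelope spectrum peaks at the flicker rate
  w10 <- modulated_tone(10000, 40, 0.5, 1, 44100)
  expect_equal(dominant_frequency(abs(w10$samples), 44100), 40)
  # zero duty is silence
  expect_true(all(modulated_tone(8000, 40, 0, 1, 44100)$samples == 0))
  # audio-only click train: measured envelope duty recovers 4%
  w4 <- modulated_tone(8000, 40, 0.04, 1, 44100)
  m4 <- measure_waveform(w4)
  expect_lt(abs(m4$duty - 0.04), 0.005)
  expect_lt(abs(m4$fundamental_freq - 40), 0.1)
})

test_that("random flicker: cycle statistics, duty bounds, determinism", {
  r <- random_flicker(12.5, c(0, 25), 60, 40000, seed = 1)
  log <- r$cycle_log
  expect_true(all(log$on_ms == 12.5))
  expect_true(all(log$off_ms <= 25))
  expect_true(all(log$duty >= 12.5 / (12.5 + 25) - 1e-9))
  expect_true(all(log$duty <= 1))
  expect_true(min(log$duty) >= 1 / 3 - 1e-9)
  # onsets strictly increasing and matching the cycle log
  expect_true(all(diff(r$onsets) > 0))
  expect_equal(diff(r$onsets)[1] * 1000, log$on_ms[1] + log$off_ms[1])

  # seed determinism
  r2 <- random_flicker(12.5, c(0, 25), 60, 40000, seed = 1)
  expect_identical(r$samples, r2$samples)
  r3 <- random_flicker(12.5, c(0, 25), 60, 40000, seed = 2)
  expect_false(identical(r$samples, r3$samples))

  # expected cycle period: on + mean(off) = 25 ms
  r600 <- random_flicker(12.5, c(0, 25), 600, 40000, seed = 7)
  expect_equal(mean(r600$cycle_log$on_ms + r600$cycle_log$off_ms), 25,
               tolerance = 0.01)

  # degenerate off-distribution at 12.5 ms collapses to the periodic
  # 40-Hz / 50%-duty square wave
  rc <- random_flicker(12.5, c(12.5, 12.5), 1, 40000, seed = 1)
  expect_identical(rc$samples, square_wave(40, 0.5, 1, 40000)$samples)
})

test_that("single pulse geometry and carrier content", {
  p <- single_pulse("visual", 12.5, 40000)
  expect_equal(sum(p$samples > 0.5), 500)
  expect_equal(nrow(p$cycle_log), 1L)
  expect_equal(p$onsets, 0)
  expect_true(all(p$samples[501:length(p$samples)] == 0))
  # 8-kHz carrier within a 12.5-ms pulse: about 100 cycles
  pa <- single_pulse("audio", 12.5, 44100, carrier_freq = 8000)
  burst <- pa$samples[1:round(0.0125 * 44100)]
  n_cycles <- sum(abs(diff(sign(burst))) > 0) / 2
  expect_equal(n_cycles, 100, tolerance = 0.02)
})

test_that("audio/visual pairing: quantization, geometry, invertibility", {
  v <- square_wave(40, 0.5, 1, 10000)
  a <- square_wave(40, 0.5, 1, 10000)
  p0 <- pair_with_delay(v, a, 0)
  expect_identical(p0$audio$onsets, v$onsets)
  p5 <- pair_with_delay(v, a, 5)
  expect_equal((p5$audio$onsets - v$onsets) * 10000, rep(50, 40))
  # inverse delay restores onsets exactly
  back <- pair_with_delay(v, p5$audio, -5)
  expect_identical(back$audio$onsets, a$onsets)
  # 50% visual with 4% audio at zero delay: shared rising edge, audio off
  # earlier (click-train geometry)
  va <- pair_with_delay(square_wave(40, 0.5, 1, 44100),
                        modulated_tone(8000, 40, 0.04, 1, 44100), 0)
  expect_identical(va$visual$onsets, va$audio$onsets)
  last_on <- function(x) max(which(abs(x[1:1102]) > 0.5))
  expect_lt(last_on(va$audio$samples), last_on(va$visual$samples))
  expect_error(pair_with_delay(v, square_wave(40, 0.5, 1, 20000), 0),
               "sample rates")
})

test_that("waveform parameter validation", {
  expect_error(square_wave(40, 1.2, 1, 40000), "duty")
  expect_error(square_wave(40, -0.1, 1, 40000), "duty")
  expect_error(square_wave(25000, 0.5, 1, 40000), "flicker_freq")
  expect_error(modulated_tone(30000, 40, 0.5, 1, 44100), "carrier_freq")
  expect_error(random_flicker(12.5, c(10, 5), 1, 40000), "off_range")
  expect_error(waveform_spec("audio", condition = "random"), "carrier_freq")
  expect_error(waveform_spec("visual", condition = "random"), "seed")
})

test_that("generate_waveform dispatches on condition and modality", {
  s <- waveform_spec("audiovisual", 40, 0.5, carrier_freq = 8000,
                     duration = 0.5, audio_visual_delay = 5)
  w <- generate_waveform(s)
  expect_s3_class(w$visual, "stim_waveform")
  expect_equal(w$audio$modality, "audio")
  expect_lt(abs((w$audio$onsets[1] - w$visual$onsets[1]) - 0.005),
            1 / 44100)
  wr <- generate_waveform(waveform_spec("visual", condition = "random",
                                        duration = 1, seed = 3))
  expect_equal(wr$condition, "random")
  wc <- generate_waveform(waveform_spec("visual", condition = "constant",
                                        duration = 0.1))
  expect_true(all(wc$samples == 1))
})
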