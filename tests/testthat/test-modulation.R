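# Entrainment statistics: channel/subject criteria, latency, contrasts,
# spike phase locking, occluded-condition check.

test_that("channel criterion: z arithmetic, inclusive boundary, shift invariance", {
  freq <- 30:50
  base <- rep(10, length(freq))
  base[freq %in% c(31:39, 41:49)] <- 10 + rep(c(-1, 1), 9)  # mean 10, sd ~1
  sdn <- sd(rep(c(-1, 1), 9))
  make1 <- function(p40) {
    pw <- base; pw[freq == 40] <- p40
    make_psd(freq, pw)
  }
  ch <- channel_modulation(make1(10 + 4 * sdn))
  expect_equal(ch$z_score, 4)
  expect_true(ch$modulated)
  ch0 <- channel_modulation(make1(10))
  expect_equal(ch0$z_score, 0)
  expect_false(ch0$modulated)

  # boundary scan: the flag flips exactly at z = 3, inclusive
  zs <- seq(2.90, 3.10, by = 0.01)
  flags <- vapply(zs, function(z)
    channel_modulation(make1(10 + z * sdn))$modulated, logical(1))
  expect_equal(zs[min(which(flags))], 3, tolerance = 1e-9)
  expect_true(channel_modulation(make1(10 + 3 * sdn))$modulated)

  # adding a constant to the whole PSD leaves z unchanged
  p <- make1(14)
  p_shift <- p; p_shift$power_db <- p$power_db + 17.3
  expect_equal(channel_modulation(p_shift)$z_score,
               channel_modulation(p)$z_score)

  expect_error(channel_modulation(make_psd(c(40, 41), c(5, 1))),
               "2 required")
  expect_error(channel_modulation(make_psd(1:10, rep(1, 10))), "cover")
})

test_that("subject criterion: count and hemisphere clauses", {
  # 2 left + 1 right modulated: meets both clauses
  r <- subject_modulation(make_channels(c("L", "L", "L", "R", "R"),
                                        c(TRUE, TRUE, FALSE, TRUE, FALSE)))
  expect_true(r$subject_modulated)
  expect_equal(unname(r$hemisphere_counts), c(2, 1))

  # 3 left, 0 right: fails the strict each-hemisphere reading, passes the
  # permissive either-hemisphere one
  ch <- make_channels(c("L", "L", "L", "R"), c(TRUE, TRUE, TRUE, FALSE))
  expect_false(subject_modulation(ch, hemisphere_rule = "each")$subject_modulated)
  expect_true(subject_modulation(ch, hemisphere_rule = "either")$subject_modulated)

  # below the channel count
  expect_false(subject_modulation(
    make_channels(c("L", "R"), c(TRUE, TRUE)))$subject_modulated)

  # boundary scan over the number of modulated channels: flips at 3
  for (k in 1:4) {
    ch <- make_channels(rep(c("L", "R"), 3), seq_len(6) <= k)
    expect_equal(subject_modulation(ch)$subject_modulated, k >= 3)
  }

  # monotonicity: flagging one more channel never unmodulates a subject
  set.seed(7)
  for (i in 1:20) {
    flags <- runif(8) < 0.5
    ch <- make_channels(rep(c("L", "R"), 4), flags)
    before <- subject_modulation(ch)$subject_modulated
    j <- sample(which(!flags), 1)
    flags[j] <- TRUE
    after <- subject_modulation(make_channels(rep(c("L", "R"), 4),
                                              flags))$subject_modulated
    expect_true(!before || after)
  }

  expect_error(subject_modulation(make_channels(c("L", NA), c(TRUE, TRUE))),
               "hemisphere")
})

test_that("detection latency: null, saturating, and monotone in amplitude", {
  rec0 <- gen_ssep_recording(8, sample_rate = 1024, duration = 16,
                             stim_onset = 6, response_amplitude = 0,
                             seed = 61)
  expect_true(is.na(detection_latency(rec0)))

  # saturating amplitude: detected within the first few windows, and the
  # returned latency equals a direct evaluation of the criterion on
  # growing windows (the latency definition)
  rec_hi <- gen_ssep_recording(8, sample_rate = 1024, duration = 16,
                               stim_onset = 6, response_amplitude = 50,
                               seed = 61)
  lat_hi <- detection_latency(rec_hi)
  expect_lte(lat_hi, 3)
  direct <- NA_real_
  for (w in 1:10) {
    seg <- new_recording(rec_hi$data[, (6 * 1024 + 1):((6 + w) * 1024)],
                         1024, rec_hi$metadata)
    ch <- channel_modulation(multitaper_psd(seg, band = c(30, 50)))
    if (subject_modulation(ch)$subject_modulated) { direct <- w; break }
  }
  expect_equal(lat_hi, direct)

  # latency is non-increasing in response amplitude over the operating
  # range of the criterion (below leakage saturation)
  for (s in 62:64) {
    lat <- vapply(c(0.3, 1, 3), function(a) {
      r <- gen_ssep_recording(8, sample_rate = 1024, duration = 26,
                              stim_onset = 6, response_amplitude = a,
                              seed = s)
      l <- detection_latency(r)
      if (is.na(l)) 21 else l     # never-detected ranks worst
    }, numeric(1))
    expect_true(all(diff(lat) <= 0))
  }
  expect_error(detection_latency(rec0, onset = 99), "onset")
})

test_that("condition contrast matches hand-computed paired statistics", {
  r <- condition_contrast(c(2, 3, 4), c(1, 1, 1))
  # differences {1,2,3}: mean 2, sd 1 -> paired d = 2; t = 2/(1/sqrt(3))
  expect_equal(r$cohens_d, 2)
  expect_equal(r$paired_t_p, 2 * pt(-2 / (1 / sqrt(3)), df = 2),
               tolerance = 1e-10)
  expect_equal(unname(r$medians["stim"]), 3)
  expect_equal(r$quartiles$stim, c(2.5, 3.5))

  same <- condition_contrast(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$cohens_d, 0)
  expect_equal(same$paired_t_p, 1)

  # shifting the control flips the sign of d with the shift
  set.seed(3)
  x <- rnorm(10)
  up <- condition_contrast(x, x + 2)$cohens_d
  dn <- condition_contrast(x, x - 2)$cohens_d
  expect_lt(up, 0)
  expect_gt(dn, 0)
  expect_error(condition_contrast(1:3, 1:4), "equal")
  expect_error(condition_contrast(1, 2), "at least 2")
})

test_that("spike phase locking: limits, closed form, Rayleigh null", {
  # all spikes at one phase
  st <- spike_phase_locking(seq(0.0125, 10, by = 0.025), 40, 0)
  expect_equal(st$vector_strength, 1, tolerance = 1e-9)
  expect_lt(st$uniformity_p, 1e-6)
  expect_equal(cos(st$preferred_phase - pi), 1, tolerance = 1e-9)

  # uniform phases: VS near zero, Rayleigh p large
  set.seed(9)
  u <- sort(runif(5000, 0, 100))
  su <- spike_phase_locking(u, 40, 0)
  expect_lt(su$vector_strength, 0.05)
  expect_gt(su$uniformity_p, 0.01)

  # full cosine modulation: asymptotic vector strength 1/2
  sp <- gen_phase_locked_spikes(50, 1, 40, 0, 600, seed = 71)
  sm <- spike_phase_locking(sp$times, 40, 0)
  expect_equal(sm$vector_strength, 0.5, tolerance = 0.03)
  # and the preferred phase is recovered
  sp2 <- gen_phase_locked_spikes(50, 1, 40, pi / 3, 600, seed = 72)
  sm2 <- spike_phase_locking(sp2$times, 40, 0)
  expect_equal(sm2$preferred_phase, pi / 3, tolerance = 0.05)

  few <- spike_phase_locking(c(0.1, 0.2, 0.3), 40, 0)
  expect_true(few$insufficient_data)
  expect_error(spike_phase_locking(c(2, 1), 40), "sorted")
})

test_that("occluded-condition check flags frequency-specific artifacts", {
  # clean occluded recording: no artifact
  rec0 <- gen_ssep_recording(6, sample_rate = 1024, duration = 12,
                             stim_onset = 0, response_amplitude = 0,
                             seed = 81)
  expect_false(occluded_check(multitaper_psd(rec0, band = c(2, 100))))

  # a 40-Hz electrical artifact on one channel trips the check at 40 Hz
  reca <- gen_ssep_recording(6, sample_rate = 1024, duration = 12,
                             stim_onset = 0,
                             response_amplitude = c(5, 0, 0, 0, 0, 0),
                             seed = 81)
  psda <- multitaper_psd(reca, band = c(2, 100))
  expect_true(occluded_check(psda, stim_freq = 40))
  # but not at a different stimulation frequency
  expect_false(occluded_check(psda, stim_freq = 80,
                              neighbor_bands = list(c(71, 79), c(81, 89))))
})
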