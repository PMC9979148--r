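# Open-field analysis: inactivity bouts, activity/zone percentages,
# repeated-measures comparison.

test_that("inactivity classification: stationary, moving, and boundary cases", {
  # perfectly stationary 10-s trajectory: one bout covering the record
  still <- make_traj(rep("still", 301))
  b <- classify_inactivity(still)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$end), c(0, 10))

  # constant-velocity walk: no bouts
  n <- 301
  walk <- new_trajectory(data.frame(t = (0:(n - 1)) / 30,
                                    x = seq(1, 29, length.out = n),
                                    y = rep(15, n)), c(30, 30))
  expect_equal(nrow(classify_inactivity(walk)), 0)

  # duration boundary is strict: a 0.5-s stationary interval is not a
  # bout, anything longer is
  for (d in c(0.4, 0.5)) {
    states <- c(rep("move", 60), rep("still", d * 30 + 1), rep("move", 60))
    expect_equal(nrow(classify_inactivity(make_traj(states))), 0)
  }
  for (d in c(0.6, 1.0)) {
    states <- c(rep("move", 60), rep("still", d * 30 + 1), rep("move", 60))
    b <- classify_inactivity(make_traj(states))
    expect_equal(nrow(b), 1)
    expect_equal(b$duration, d)
  }

  # tracking gaps split candidate bouts
  tg <- make_traj(rep("still", 301))
  tg$data$t[151:301] <- tg$data$t[151:301] + 1   # 1-s dropout
  bg <- classify_inactivity(tg)
  expect_equal(nrow(bg), 2)
  expect_error(classify_inactivity(make_traj("still")), "2 frames")
})

test_that("bounding-disc option makes the stationarity test rotation invariant", {
  # diagonal micro-drift whose box area stays tiny but measures the same
  # after rotation under the disc method
  n <- 61
  base <- data.frame(t = (0:(n - 1)) / 30,
                     x = 10 + seq(0, 0.02, length.out = n),
                     y = 10 + seq(0, 0.02, length.out = n))
  rot <- base
  ang <- pi / 7
  rot$x <- 10 + cos(ang) * (base$x - 10) - sin(ang) * (base$y - 10)
  rot$y <- 10 + sin(ang) * (base$x - 10) + cos(ang) * (base$y - 10)
  b1 <- classify_inactivity(new_trajectory(base, c(30, 30)), method = "disc")
  b2 <- classify_inactivity(new_trajectory(rot, c(30, 30)), method = "disc")
  expect_equal(nrow(b1), nrow(b2))
  expect_equal(b1$duration, b2$duration, tolerance = 1e-9)
})

test_that("activity percentage arithmetic and the exact complement identity", {
  tr <- make_traj(rep("move", 301))
  expect_equal(percent_time_active(tr, data.frame(duration = numeric(0))), 100)
  expect_equal(percent_time_active(tr, data.frame(duration = 10)), 0)
  # one 15-min bout in a 60-min record: 75% active
  expect_equal(percent_time_active(
    new_trajectory(data.frame(t = seq(0, 3600, by = 1),
                              x = rep(1, 3601), y = rep(1, 3601)),
                   c(30, 30)),
    data.frame(duration = 900)), 75)
  # active% + inactive% = 100 exactly (1-s bout in an 8-s record)
  states <- c(rep("move", 105), rep("still", 31), rep("move", 105))
  tr2 <- make_traj(states)
  bouts <- classify_inactivity(tr2)
  expect_equal(bouts$duration, 1)
  inactive <- 100 * sum(bouts$duration) / diff(range(tr2$data$t))
  expect_identical(percent_time_active(tr2, bouts) + inactive, 100)
})

test_that("center-zone occupancy counts frames inside, boundary inclusive", {
  inzone <- new_trajectory(data.frame(t = 0:10 / 30, x = rep(15, 11),
                                      y = rep(15, 11)), c(30, 30))
  expect_equal(percent_time_in_zone(inzone), 100)
  edge <- new_trajectory(data.frame(t = 0:10 / 30, x = rep(2, 11),
                                    y = rep(2, 11)), c(30, 30))
  expect_equal(percent_time_in_zone(edge), 0)
  # half the frames inside by construction
  half <- new_trajectory(data.frame(t = 0:9 / 30,
                                    x = rep(c(15, 1), 5),
                                    y = rep(15, 10)), c(30, 30))
  expect_equal(percent_time_in_zone(half), 50)
  # default center zone is the central 50% linear-dimension rectangle
  expect_equal(inzone$center_zone, c(7.5, 7.5, 22.5, 22.5))
  expect_error(percent_time_in_zone(inzone, c(10, 10, 10, 20)), "degenerate")
  expect_error(percent_time_in_zone(inzone, c(10, 10, 40, 20)), "outside")
})

test_that("repeated-measures ANOVA matches hand sums of squares", {
  # hand-sized table: 3 subjects x 2 conditions
  v <- c(1, 2, 2, 4, 3, 3)
  subj <- c("s1", "s1", "s2", "s2", "s3", "s3")
  cond <- rep(c("c1", "c2"), 3)
  r <- compare_conditions(v, subj, cond)
  expect_equal(r$F, rm_anova_by_hand(v, subj, cond))
  expect_equal(r$F, 3)           # SS_cond/1 = 1.5, SS_err/2 = 0.5
  expect_equal(r$df, c(1, 2))

  # identical values across conditions: F = 0
  expect_equal(compare_conditions(c(1, 1, 2, 2, 3, 3), subj, cond)$F, 0)

  # larger randomized design agrees with the hand computation
  set.seed(13)
  v2 <- rnorm(20)
  subj2 <- rep(paste0("m", 1:5), each = 4)
  cond2 <- rep(letters[1:4], 5)
  r2 <- compare_conditions(v2, subj2, cond2)
  expect_equal(r2$F, rm_anova_by_hand(v2, subj2, cond2))
  expect_equal(r2$df, c(3, 12))
  expect_equal(r2$p, pf(r2$F, 3, 12, lower.tail = FALSE))

  # relabeling conditions leaves F invariant
  relab <- c(a = "w", b = "x", c = "y", d = "z")[cond2]
  expect_equal(compare_conditions(v2, subj2, relab)$F, r2$F)

  expect_error(compare_conditions(v2[-1], subj2[-1], cond2[-1]), "balanced")
})
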