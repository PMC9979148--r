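# Shared fixtures, all built in code.

# PSD object with arbitrary power values, for constructed-arithmetic tests.
make_psd <- function(freq, power, hemisphere = NULL) {
  power <- as.matrix(power)
  n_ch <- ncol(power)
  if (is.null(hemisphere)) hemisphere <- rep(c("L", "R"), length.out = n_ch)
  structure(list(freq = freq, power_db = power,
                 channel_id = paste0("ch", seq_len(n_ch)),
                 hemisphere = hemisphere,
                 params = list(band = range(freq), time_bandwidth = 3,
                               n_tapers = 5,
                               resolution_hz = diff(freq[1:2]))),
            class = "psd_result")
}

# Channel-modulation table with given hemisphere labels and flags.
make_channels <- function(hemisphere, modulated) {
  n <- length(hemisphere)
  data.frame(channel_id = paste0("ch", seq_len(n)), hemisphere = hemisphere,
             power_at_stim = ifelse(modulated, 14, 10), neighbor_mean = 10,
             neighbor_sd = 1, z_score = ifelse(modulated, 4, 0),
             modulated = modulated)
}

# Hand-built trajectory: stationary frames at one point, move frames on a
# wide grid, 30 fps.
make_traj <- function(states, frame_rate = 30, arena = c(30, 30)) {
  n <- length(states)
  t <- (seq_len(n) - 1) / frame_rate
  x <- numeric(n); y <- numeric(n)
  pos <- c(5, 5)
  for (i in seq_len(n)) {
    # reposition on move frames and on entry into a still run, so the last
    # move frame never sits inside the stationary bounding region
    if (states[i] == "move" || (i > 1 && states[i - 1] == "move"))
      pos <- c(5 + (i %% 5) * 4, 5 + (i %% 3) * 6)
    x[i] <- pos[1]; y[i] <- pos[2]
  }
  new_trajectory(data.frame(t = t, x = x, y = y), arena)
}

# Hand computation of the one-way repeated-measures F statistic.
rm_anova_by_hand <- function(values, subject, condition) {
  subject <- factor(subject); condition <- factor(condition)
  grand <- mean(values)
  n_s <- nlevels(subject); n_c <- nlevels(condition)
  ss_cond <- n_s * sum((tapply(values, condition, mean) - grand)^2)
  ss_subj <- n_c * sum((tapply(values, subject, mean) - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- n_c - 1; df2 <- (n_s - 1) * (n_c - 1)
  (ss_cond / df1) / (ss_err / df2)
}
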