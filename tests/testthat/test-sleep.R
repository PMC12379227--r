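# Sleep module: epoch features, threshold scoring, bouts, architecture,
# state spectra and the SWA time course.

make_sine_recording <- function(freq_hz, n_s = 30, fs = 256, emg = 0) {
  t <- (seq_len(n_s * fs) - 1) / fs
  recording(tibble::tibble(eeg = sin(2 * pi * freq_hz * t),
                           emg = rep(emg, length(t))), fs)
}

test_that("epoch features separate bands and handle zero EMG", {
  rec <- make_sine_recording(2)
  f <- epoch_features(rec, epoch_length_s = 5)
  expect_equal(nrow(f), 6)
  expect_true(all(f$delta_power > 100 * f$theta_power))
  expect_true(all(f$emg_rms == 0))

  expect_error(epoch_features(recording(tibble::tibble(eeg = rnorm(1000)),
                                        200), 1), "emg")
})

test_that("trailing partial epochs are dropped", {
  rec <- make_sine_recording(2, n_s = 17)
  expect_equal(nrow(epoch_features(rec, epoch_length_s = 5)), 3)
})

test_that("synthetic REM is theta-dominated", {
  h <- hypnogram(rep("REM", 60), epoch_length_s = 5)
  rec <- sim_eeg_emg(h, 256, seed = 2)
  f <- epoch_features(rec, 5)
  expect_gt(median(f$theta_delta_ratio), 1)
})

test_that("scoring rule order: EMG dominates, +Inf thresholds fall through to REM", {
  f <- tibble::tibble(epoch = 1:3, t_start_s = c(0, 5, 10),
                      delta_power = c(10, 10, 1),
                      theta_power = c(1, 1, 10),
                      theta_delta_ratio = c(0.1, 0.1, 10),
                      emg_rms = c(5, 0.01, 0.01),
                      eeg_amplitude = 1)
  attr(f, "epoch_length_s") <- 5
  th <- list(emg_rms_hi = 1, delta_ratio_hi = 2, theta_ratio_hi = NA)
  h <- score_epochs(f, th)
  expect_equal(h$state, c("WAKE", "NREM", "REM"))

  h_inf <- score_epochs(f, list(emg_rms_hi = Inf, delta_ratio_hi = Inf,
                                theta_ratio_hi = Inf))
  expect_true(all(h_inf$state == "REM"))
})

test_that("auto-calibrated scoring recovers generator truth on 2,000 epochs", {
  h <- sim_hypnogram(2000 * 5, epoch_length_s = 5, seed = 10)
  rec <- sim_eeg_emg(h, sample_rate_hz = 256, seed = 11)
  scored <- score_recording(rec, 5)
  expect_gte(mean(scored$state == h$state), 0.95)
})

test_that("scoring is permutation-equivariant", {
  h <- sim_hypnogram(300 * 5, epoch_length_s = 5, seed = 12)
  rec <- sim_eeg_emg(h, 256, seed = 13)
  f <- epoch_features(rec, 5)
  th <- attr(score_epochs(f), "thresholds")
  perm <- sample(nrow(f))
  fp <- f[perm, ]
  fp$epoch <- seq_len(nrow(fp))
  fp$t_start_s <- f$t_start_s
  attr(fp, "epoch_length_s") <- 5
  expect_identical(score_epochs(fp, th)$state,
                   score_epochs(f, th)$state[perm])
})

test_that("bout extraction matches examples and the run-length oracle", {
  h <- hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "NREM", "REM"),
                 epoch_length_s = 5)
  b <- extract_bouts(h)
  expect_equal(b$state, c("WAKE", "NREM", "REM"))
  expect_equal(b$start_s, c(0, 10, 25))
  expect_equal(b$end_s, c(10, 25, 30))

  expect_equal(nrow(extract_bouts(hypnogram(rep("NREM", 50)))), 1)

  alt <- hypnogram(rep(c("WAKE", "NREM"), 25), epoch_length_s = 5)
  expect_equal(nrow(extract_bouts(alt)), 50)

  withr::with_seed(99, {
    for (i in 1:100) {
      labels <- sample(c("WAKE", "NREM", "REM"), 80, replace = TRUE)
      h <- hypnogram(labels, epoch_length_s = 5)
      got <- extract_bouts(h)
      want <- rle_bouts_oracle(labels, 5)
      expect_equal(got$state, want$state)
      expect_equal(got$start_s, want$start_s)
      expect_equal(got$end_s, want$end_s)
    }
  })
})

test_that("short bouts merge into the longer neighbour, ties preceding", {
  # NREM(3) WAKE(1) NREM(2): short WAKE joins the longer left NREM run
  h <- hypnogram(c("NREM", "NREM", "NREM", "WAKE", "NREM", "NREM"),
                 epoch_length_s = 5)
  b <- extract_bouts(h, min_bout_s = 10)
  expect_equal(nrow(b), 1)
  expect_equal(b$state, "NREM")
  expect_equal(b$duration_s, 30)

  # tie between neighbours -> preceding absorbs
  h2 <- hypnogram(c("WAKE", "WAKE", "REM", "NREM", "NREM"),
                  epoch_length_s = 5)
  b2 <- extract_bouts(h2, min_bout_s = 10)
  expect_equal(b2$state, c("WAKE", "NREM"))
  expect_equal(b2$duration_s, c(15, 10))
})

test_that("architecture statistics are exact and conserve time", {
  aw <- hypnogram(rep("WAKE", 100), epoch_length_s = 5)
  s <- architecture_stats(aw)
  expect_equal(s$percent_time[s$state == "WAKE"], 100)
  expect_equal(s$bout_count[s$state == "NREM"], 0)
  expect_true(is.na(s$latency_s[s$state == "NREM"]))

  half <- hypnogram(rep(c("NREM", "WAKE"), each = 50), epoch_length_s = 5)
  s2 <- architecture_stats(half)
  expect_equal(s2$percent_time[s2$state == "NREM"], 50)

  withr::with_seed(7, {
    for (i in 1:50) {
      labels <- sample(c("WAKE", "NREM", "REM"), 120, replace = TRUE)
      got <- as.data.frame(architecture_stats(hypnogram(labels, 5)))
      want <- architecture_oracle(labels, 5)
      expect_equal(got$percent_time, want$percent_time)
      expect_equal(got$bout_count, want$bout_count)
      expect_equal(got$mean_bout_duration_s, want$mean_bout_duration_s)
      expect_equal(got$latency_s, want$latency_s)
      expect_equal(sum(got$percent_time), 100)
    }
  })
})

test_that("state PSD localises a pure tone and satisfies Parseval", {
  fs <- 256
  t <- (seq_len(fs * 60) - 1) / fs
  rec <- recording(tibble::tibble(eeg = sin(2 * pi * 2 * t),
                                  emg = rep(0, length(t))), fs)
  h <- hypnogram(rep("NREM", 12), epoch_length_s = 5)
  psd <- state_psd(rec, h, "NREM", window_s = 4)
  expect_lt(abs(psd$freq_hz[which.max(psd$power)] - 2), 0.25 + 1e-9)

  # Parseval: integral of the PSD approximates the variance
  withr::with_seed(5, x <- rnorm(fs * 30))
  p2 <- welch_psd(x, fs, window_s = 4)
  total <- sum(p2$power) * (p2$freq_hz[2] - p2$freq_hz[1])
  expect_equal(total, var(x), tolerance = 0.1)

  expect_error(state_psd(rec, hypnogram(rep("NREM", 12), 5), "REM"),
               "Insufficient data")
})

test_that("white-noise PSD is flat on average", {
  fs <- 128
  withr::with_seed(21, {
    ratios <- replicate(20, {
      p <- welch_psd(rnorm(fs * 60), fs, window_s = 2)
      keep <- p$freq_hz > 0 & p$freq_hz < fs / 2
      max(p$power[keep]) / min(p$power[keep])
    })
  })
  expect_lt(median(ratios), 10)
})

test_that("band power matches a direct bin-averaging oracle", {
  p <- welch_psd(rnorm(2000), 100, window_s = 2)
  expect_equal(band_power(p, 1, 4),
               mean(p$power[p$freq_hz >= 1 & p$freq_hz < 4]))
  flat <- tibble::tibble(freq_hz = seq(0, 50, by = 0.5), power = 3.3)
  expect_equal(band_power(flat, 1, 4), 3.3)
  expect_equal(band_power(flat, 10, 20), 3.3)
  expect_error(band_power(flat, 60, 70), "band")
})

test_that("SWA time course scales with squared delta amplitude", {
  el <- 5
  n_ep <- 480   # 40 min at 5 s epochs
  h <- hypnogram(rep("NREM", n_ep), epoch_length_s = el)
  gain <- rep(1, n_ep)
  gain[1:120] <- 1.5   # first 10 min boosted
  base_rec <- sim_eeg_emg(h, 256, seed = 31)
  boost_rec <- sim_eeg_emg(h, 256, seed = 31, delta_gain = gain)
  baseline <- mean(swa_timecourse(base_rec, h, baseline = 1,
                                  bin_s = 600)$delta_power)
  swa <- swa_timecourse(boost_rec, h, baseline = baseline, bin_s = 600)
  expect_equal(swa$swa_pct[1], 225, tolerance = 0.1 * 225)
  expect_equal(mean(swa$swa_pct[-1]), 100, tolerance = 10)

  # identical recording, whole recording as its own baseline interval
  swa0 <- swa_timecourse(base_rec, h, baseline = c(0, n_ep * el),
                         bin_s = n_ep * el)
  expect_equal(swa0$swa_pct, 100)

  # bins without NREM are missing, not zero
  h2 <- hypnogram(c(rep("WAKE", 120), rep("NREM", 360)), epoch_length_s = el)
  swa2 <- swa_timecourse(base_rec, h2, baseline = baseline, bin_s = 600)
  expect_true(is.na(swa2$swa_pct[1]))
})
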