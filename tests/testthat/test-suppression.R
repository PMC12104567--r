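# The amplitude-duration suppression rule: inclusive +/-15 uV threshold,
# strictly > 0.2 s duration, half-open event intervals in seconds.

test_that("hand-enumerable fixtures yield exactly the expected events", {
  fs <- 250
  # all-zero trace: one event spanning the whole record
  rec <- eeg_recording(rep(0, 20 * fs), fs)
  ev <- detect_suppressions(rec, filter = FALSE)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_s, 0)
  expect_equal(ev$offset_s, 20)
  expect_equal(ev$duration_s, 20)

  # 50-uV 10-Hz sinusoid: each sub-threshold run near a zero crossing lasts
  # ~ 2*asin(15/50)/(2*pi*10) ~ 0.0097 s < 0.2 s, so no events
  t <- (0:(10 * fs - 1)) / fs
  rec <- eeg_recording(50 * sin(2 * pi * 10 * t), fs)
  ev <- detect_suppressions(rec, filter = FALSE)
  expect_equal(nrow(ev), 0L)

  # burst noise / 1.0 s of exact zeros / burst noise, with the gap flanked
  # by supra-threshold samples: exactly one event of exactly 1.0 s
  set.seed(2)
  x <- c(rnorm(5 * fs, sd = 40), rep(0, fs), rnorm(5 * fs, sd = 40))
  rec <- eeg_recording(x, fs)
  ev <- detect_suppressions(rec, filter = FALSE)
  oracle <- scan_events_bruteforce(x, fs)
  expect_equal(as.data.frame(ev)[names(oracle)], oracle)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$duration_s - 1.0), 1 / fs + 1e-12)
})

test_that("threshold is inclusive and duration strictly greater-than", {
  fs <- 250
  # samples exactly at 15 uV count as suppressed
  x <- c(rep(100, 100), rep(15, 60), rep(100, 100))
  ev <- detect_suppressions(eeg_recording(x, fs), filter = FALSE)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_s, 60 / fs)
  # a run of exactly 0.2 s (50 samples at 250 Hz) is discarded; 51 kept
  x50 <- c(rep(100, 100), rep(0, 50), rep(100, 100))
  x51 <- c(rep(100, 100), rep(0, 51), rep(100, 100))
  expect_equal(nrow(detect_suppressions(eeg_recording(x50, fs), filter = FALSE)), 0L)
  expect_equal(nrow(detect_suppressions(eeg_recording(x51, fs), filter = FALSE)), 1L)
})

test_that("event lists match the brute-force scanner on random traces", {
  for (seed in 1:50) {
    x <- random_mixed_trace(seed)
    ev <- detect_suppressions(eeg_recording(x, 250), filter = FALSE)
    oracle <- scan_events_bruteforce(x, 250)
    expect_equal(as.data.frame(ev)[names(oracle)], oracle,
                 info = sprintf("seed %d", seed))
  }
})

test_that("detection is monotone in threshold and minimum duration", {
  win <- c(0, 10)
  for (seed in 1:10) {
    x <- random_mixed_trace(seed)
    rec <- eeg_recording(x, 250)
    tot <- vapply(c(5, 10, 15, 25), function(thr) {
      cumulative_suppression_time(
        detect_suppressions(rec, threshold_uv = thr, filter = FALSE), win)
    }, numeric(1))
    expect_true(all(diff(tot) >= -1e-12))
    tot_d <- vapply(c(0, 0.1, 0.2, 0.5), function(md) {
      cumulative_suppression_time(
        detect_suppressions(rec, min_duration_s = md, filter = FALSE), win)
    }, numeric(1))
    expect_true(all(diff(tot_d) <= 1e-12))
  }
})

test_that("shifting a trace in time shifts events by the same amount", {
  set.seed(7)
  x <- random_mixed_trace(7)
  fs <- 250
  shift_n <- 500L                     # 2 s of supra-threshold padding
  x_shift <- c(rep(100, shift_n), x)
  ev <- detect_suppressions(eeg_recording(x, fs), filter = FALSE)
  ev_s <- detect_suppressions(eeg_recording(x_shift, fs), filter = FALSE)
  expect_equal(ev_s$onset_s, ev$onset_s + shift_n / fs)
  expect_equal(ev_s$offset_s, ev$offset_s + shift_n / fs)
})

test_that("cumulative suppression time clips events to the window", {
  ev <- data.frame(onset_s = c(10, 30), offset_s = c(20, 35))
  ev$duration_s <- ev$offset_s - ev$onset_s
  expect_equal(cumulative_suppression_time(ev, c(0, 60)), 15)
  ev2 <- data.frame(onset_s = 18, offset_s = 25, duration_s = 7)
  expect_equal(cumulative_suppression_time(ev2, c(20, 60)), 5)
  expect_equal(cumulative_suppression_time(ev[0, ], c(0, 60)), 0)
  # unsorted or overlapping events are rejected
  bad <- data.frame(onset_s = c(30, 10), offset_s = c(35, 20))
  expect_error(cumulative_suppression_time(bad, c(0, 60)), "sorted")
  bad2 <- data.frame(onset_s = c(10, 15), offset_s = c(20, 25))
  expect_error(cumulative_suppression_time(bad2, c(0, 60)), "non-overlapping")
})

test_that("global BSR is the suppressed fraction in percent", {
  ev <- data.frame(onset_s = c(10, 30), offset_s = c(20, 35))
  expect_equal(bsr_global(ev, c(0, 60)), 25)
  full <- data.frame(onset_s = 0, offset_s = 60)
  expect_equal(bsr_global(full, c(0, 60)), 100)
  expect_error(bsr_global(ev, c(10, 10)), "window")
})

test_that("windowed BSR partitions back to the global BSR", {
  fs <- 250
  set.seed(11)
  cfg <- bs_preset("aged", seed = 11, duration_s = 400,
                   anesthesia_start_s = 60, anesthesia_len_s = 300)
  sim <- simulate_bs_eeg(cfg)
  ev <- detect_suppressions(sim$recording)
  # non-overlapping windows (step = win) partition the anesthesia interval
  tc <- bsr_timecourse(sim$recording, ev, win_s = 60, step_s = 60)
  expect_equal(mean(tc$bsr_percent), bsr_global(ev, c(60, 360)),
               tolerance = 1e-9)
  # full suppression gives 100% in every window
  rec0 <- eeg_recording(rep(0, 120 * fs), fs, anesthesia_start_s = 0,
                        anesthesia_end_s = 120)
  ev0 <- detect_suppressions(rec0, filter = FALSE)
  tc0 <- bsr_timecourse(rec0, ev0, win_s = 30, step_s = 10)
  expect_true(all(tc0$bsr_percent == 100))
  expect_error(bsr_timecourse(rec0, ev0, win_s = 500), "exceeds")
})

test_that("suppression summary satisfies the BSR identity", {
  cfg <- bs_preset("young", seed = 3, duration_s = 400,
                   anesthesia_start_s = 60, anesthesia_len_s = 300)
  sim <- simulate_bs_eeg(cfg)
  s <- suppression_summary(sim$recording)
  expect_equal(s$bsr_percent,
               100 * s$total_suppression_time_s / (s$window[2] - s$window[1]),
               tolerance = 1e-9)
  expect_lte(s$total_suppression_time_s, s$window[2] - s$window[1])
  expect_gte(s$bsr_percent, 0)
  expect_lte(s$bsr_percent, 100)
})
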