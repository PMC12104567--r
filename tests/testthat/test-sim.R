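# Synthetic-cohort generator: seeded determinism, state-duration renewal
# structure, amplitude regimes, and the cohort writer.

test_that("generators are pure functions of config and seed", {
  cfg <- bs_preset("aged", seed = 5, duration_s = 120,
                   anesthesia_start_s = 20, anesthesia_len_s = 90)
  a <- simulate_bs_eeg(cfg)
  b <- simulate_bs_eeg(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$ground_truth$state_labels, b$ground_truth$state_labels)
  cfg2 <- cfg; cfg2$seed <- 6L
  expect_false(identical(simulate_bs_eeg(cfg2)$recording$samples,
                         a$recording$samples))
  pc <- photometry_preset("aged", seed = 5, duration_s = 60,
                          anesthesia_start_s = 10, anesthesia_len_s = 40)
  expect_identical(simulate_photometry(pc)$trace$f_au,
                   simulate_photometry(pc)$trace$f_au)
  # the global RNG stream is left untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_bs_eeg(cfg))
  expect_identical(.Random.seed, before)
})

test_that("suppression-state samples stay within the +/-15 uV criterion", {
  cfg <- bs_sim_config(seed = 8, duration_s = 1200, anesthesia_start_s = 0,
                       anesthesia_end_s = 1200, mean_suppression_s = 6,
                       mean_burst_s = 4, duration_law = "gamma",
                       sigma_suppression_uv = 4)
  sim <- simulate_bs_eeg(cfg)
  supp <- sim$ground_truth$state_labels == "suppression"
  expect_gt(sum(supp), 1e5)          # enough samples for the tail estimate
  frac <- mean(abs(sim$recording$samples[supp]) <= 15)
  expect_gt(frac, 0.999)             # Gaussian tail beyond 15/4 = 3.75 SD
})

test_that("ground-truth BSR obeys the renewal-reward limit", {
  # mean 5 s suppression / 5 s burst -> 50% asymptotically; at a 20-min
  # window the sampling SD is ~3 points, so the mean over seeds is tight
  # and nearly all seeds fall within +/-10 points
  v <- vapply(1:100, function(s) {
    cfg <- bs_sim_config(seed = s, duration_s = 1200, anesthesia_start_s = 0,
                         anesthesia_end_s = 1200, mean_suppression_s = 5,
                         mean_burst_s = 5, duration_law = "exponential")
    simulate_bs_states(cfg)$true_bsr_percent
  }, numeric(1))
  expect_lt(abs(mean(v) - 50), 2)
  expect_lt(sd(v), 5)
  expect_gte(sum(abs(v - 50) <= 10), 95)
})

test_that("detector recovers simulated ground truth per sample", {
  for (grp in c("aged", "young")) {
    cfg <- bs_preset(grp, seed = 4)
    sim <- simulate_bs_eeg(cfg)
    ev <- detect_suppressions(sim$recording)
    w <- c(cfg$anesthesia_start_s, cfg$anesthesia_end_s)
    expect_lt(abs(bsr_global(ev, w) - sim$ground_truth$true_bsr_percent), 5)
    fs <- cfg$fs_hz
    n <- length(sim$recording$samples)
    detmask <- logical(n)
    for (k in seq_len(nrow(ev))) {
      detmask[(floor(ev$onset_s[k] * fs) + 1):ceiling(ev$offset_s[k] * fs)] <- TRUE
    }
    tsamp <- (seq_len(n) - 1) / fs
    inwin <- tsamp >= w[1] & tsamp < w[2]
    lab <- sim$ground_truth$state_labels
    sens <- mean(detmask[lab == "suppression" & inwin])
    spec <- mean(!detmask[lab != "suppression" & inwin])
    expect_gt(sens, 0.90)
    expect_gt(spec, 0.90)
  }
})

test_that("photometry simulation matches its closed form", {
  # no decline, no bleach, no noise: constant trace at f0
  pc <- photometry_sim_config(seed = 1, duration_s = 60, f0_au = 100)
  sim <- simulate_photometry(pc)
  expect_equal(sim$trace$f_au, rep(100, 6000))
  # 20% decline with tau small relative to the window: late mean ~ 0.8 f0
  pc2 <- photometry_sim_config(seed = 1, duration_s = 600, f0_au = 100,
                               decline_fraction = 0.2, decline_onset_s = 0,
                               decline_tau_s = 10)
  sim2 <- simulate_photometry(pc2)
  late <- sim2$trace$f_au[sim2$trace$fs_hz * 300 + seq_len(100 * 30000 / 100)]
  expect_equal(mean(late), 80, tolerance = 0.01)
})

test_that("invalid configurations are refused naming the field", {
  expect_error(bs_sim_config(seed = 1, duration_s = 100,
                             anesthesia_start_s = 50, anesthesia_end_s = 40,
                             mean_suppression_s = 5, mean_burst_s = 5),
               "anesthesia_start_s")
  expect_error(bs_sim_config(seed = 1, duration_s = 100,
                             anesthesia_start_s = 0, anesthesia_end_s = 100,
                             mean_suppression_s = 5, mean_burst_s = 5,
                             sigma_suppression_uv = 6),
               "sigma_suppression_uv")
  expect_error(bs_sim_config(seed = 1, duration_s = 100,
                             anesthesia_start_s = 0, anesthesia_end_s = 100,
                             mean_suppression_s = 5, mean_burst_s = 5,
                             band_weights = c(delta = 0.5, theta = 0.5,
                                              alpha = 0.5, beta = 0.5)),
               "band_weights")
  expect_error(photometry_sim_config(seed = 1, duration_s = 60,
                                     decline_fraction = 1.2),
               "decline_fraction")
})

test_that("the cohort writer emits every declared file reproducibly", {
  spec <- small_cohort(seed = 21)
  d1 <- file.path(tempfile(), "c1"); d2 <- file.path(tempfile(), "c2")
  m1 <- simulate_cohort(spec, d1)
  m2 <- simulate_cohort(spec, d2)
  expect_equal(sum(grepl("_eeg\\.tsv$", m1$files)), 6L)
  expect_equal(sum(grepl("_photometry\\.tsv$", m1$files)), 6L)
  expect_true("emergence.tsv" %in% m1$files)
  for (f in m1$files) {
    expect_true(file.exists(file.path(d1, f)), info = f)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # group-mean ground-truth BSR separation between presets (60% vs 20%)
  gt_bsr <- vapply(m1$groups, function(g) {
    mean(vapply(g$subjects, function(s) {
      jsonlite::read_json(file.path(d1, s$ground_truth))$true_bsr_percent
    }, numeric(1)))
  }, numeric(1))
  names(gt_bsr) <- vapply(m1$groups, `[[`, character(1), "label")
  expect_gt(gt_bsr[["aged"]] - gt_bsr[["young"]], 30)
})

test_that("cohort emergence times follow the configured lognormal", {
  # lognormal(mu = ln 60, sigma = 0.1): mean = exp(mu + sigma^2/2) ~ 60.3 s
  grp <- list(label = "g", n_subjects = 100L,
              bs_config = bs_preset("aged", duration_s = 30,
                                    anesthesia_start_s = 5,
                                    anesthesia_len_s = 20),
              phot_config = photometry_preset("young", duration_s = 30,
                                              anesthesia_start_s = 5,
                                              anesthesia_len_s = 20),
              emergence_meanlog = log(60), emergence_sdlog = 0.1)
  d <- tempfile()
  simulate_cohort(cohort_spec(list(grp), seed = 31), d)
  em <- read_measure_table(file.path(d, "emergence.tsv"),
                           c("subject_id", "rrr_time_s"))
  expect_equal(nrow(em), 100L)
  m <- mean(as.numeric(em$rrr_time_s))
  expect_gt(m, 55)
  expect_lt(m, 66)
})
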