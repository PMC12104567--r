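# dF/F computation and pre/during-anesthesia quantification.

test_that("dF/F reproduces (F - F0)/F0 exactly on constructed traces", {
  tr <- photometry_trace(rep(100, 1000), 100, anesthesia_start_s = 5,
                         anesthesia_end_s = 9)
  dff <- compute_dff(tr)
  expect_equal(dff$f0_au, 100)
  expect_true(all(dff$dff == 0))
  # F = 110 everywhere except a baseline at 100
  f <- c(rep(100, 500), rep(110, 500))
  tr2 <- photometry_trace(f, 100)
  dff2 <- compute_dff(tr2, baseline_window = c(0, 5))
  expect_equal(dff2$dff[501:1000], rep(0.1, 500), tolerance = 1e-12)
  # nonpositive baseline refused
  trz <- photometry_trace(c(rep(0, 500), rep(10, 500)) - 0, 100)
  expect_error(compute_dff(trz, baseline_window = c(0, 5)), "baseline mean")
  expect_error(compute_dff(tr2, baseline_window = c(9, 20)), "outside")
})

test_that("dF/F is invariant to rescaling the fluorescence", {
  set.seed(10)
  f <- 100 + cumsum(rnorm(2000, sd = 0.05))
  tr <- photometry_trace(f, 100)
  d1 <- compute_dff(tr, baseline_window = c(0, 5))$dff
  tr2 <- photometry_trace(f * 37.5, 100)
  d2 <- compute_dff(tr2, baseline_window = c(0, 5))$dff
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("epoch change measures the during-minus-pre difference", {
  f <- c(rep(100, 1000), rep(95, 1000))   # -5% step at t = 10 s
  tr <- photometry_trace(f, 100, anesthesia_start_s = 10,
                         anesthesia_end_s = 20)
  dff <- compute_dff(tr, baseline_window = c(0, 10))
  ch <- epoch_change(dff)
  expect_equal(ch$pre_mean, 0, tolerance = 1e-12)
  expect_equal(ch$change, -0.05, tolerance = 1e-9)
  # zero trace: zero change
  ch0 <- epoch_change(compute_dff(photometry_trace(rep(50, 2000), 100),
                                  baseline_window = c(0, 10)),
                      pre_window = c(0, 10), during_window = c(10, 20))
  expect_equal(ch0$change, 0)
  expect_error(epoch_change(dff, pre_window = c(0, 12),
                            during_window = c(10, 20)), "disjoint")
})

test_that("noiseless simulated decline is recovered via the closed form", {
  a0 <- 100; a1 <- 400; tau <- 60; d <- 0.15
  pc <- photometry_sim_config(seed = 1, duration_s = 450, f0_au = 200,
                              decline_fraction = d, decline_onset_s = a0,
                              decline_tau_s = tau,
                              anesthesia_start_s = a0, anesthesia_end_s = a1)
  sim <- simulate_photometry(pc)
  dff <- compute_dff(sim$trace)
  ch <- epoch_change(dff)
  len <- a1 - a0
  mean_s <- 1 - (tau / len) * (1 - exp(-len / tau))
  expect_equal(ch$change, -d * mean_s, tolerance = 0.01 * d * mean_s)
})

test_that("aged-preset simulations show a negative change in most seeds", {
  neg <- vapply(1:30, function(s) {
    pc <- photometry_preset("aged", seed = s, duration_s = 450,
                            anesthesia_start_s = 100, anesthesia_len_s = 300)
    ch <- epoch_change(compute_dff(simulate_photometry(pc)$trace))
    ch$change < 0
  }, logical(1))
  expect_gte(sum(neg), 29)  # 0.2 decline dwarfs the 1-a.u. noise
})

test_that("group mean traces carry SD/sqrt(n) standard errors", {
  mk <- function(val) {
    tr <- photometry_trace(rep(100 * (1 + val), 1000), 100,
                           anesthesia_start_s = 5, anesthesia_end_s = 9)
    d <- compute_dff(tr, baseline_window = c(0, 5))
    d$dff <- rep(val, 1000)           # constant dF/F trace
    d
  }
  # identical traces: SEM identically zero
  gm <- group_mean_trace(list(mk(0.1), mk(0.1), mk(0.1)))
  expect_true(all(gm$sem == 0))
  expect_true(all(abs(gm$mean - 0.1) < 1e-12))
  # two constants 0 and 0.2: mean 0.1, SEM = SD/sqrt(2) = 0.1
  gm2 <- group_mean_trace(list(mk(0), mk(0.2)))
  expect_true(all(abs(gm2$mean - 0.1) < 1e-12))
  expect_true(all(abs(gm2$sem - 0.1) < 1e-12))
  expect_error(group_mean_trace(list(mk(0))), "at least 2")
})

test_that("young-preset cohort mean dF/F stays near zero", {
  dffs <- lapply(1:4, function(s) {
    pc <- photometry_preset("young", seed = s, duration_s = 450,
                            anesthesia_start_s = 100, anesthesia_len_s = 300)
    compute_dff(simulate_photometry(pc)$trace)
  })
  gm <- group_mean_trace(dffs)
  # no decline: |mean| bounded by noise + mild bleach (< 3% dF/F)
  expect_lt(max(abs(gm$mean)), 0.03)
})
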