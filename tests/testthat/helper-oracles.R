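# Independent oracles and fixture builders used across the suite.

# Brute-force per-sample run scanner: walks the samples one by one, tracking
# the current sub-threshold run, and emits runs strictly longer than
# min_dur_s. Deliberately a naive loop, independent of the rle-based
# implementation path.
scan_events_bruteforce <- function(x, fs, threshold_uv = 15, min_dur_s = 0.2) {
  onsets <- numeric(0); offsets <- numeric(0)
  run_start <- NA_integer_
  n <- length(x)
  for (i in seq_len(n)) {
    inside <- abs(x[i]) <= threshold_uv
    if (inside && is.na(run_start)) run_start <- i
    closing <- (!inside && !is.na(run_start)) ||
      (inside && i == n && !is.na(run_start))
    if (closing) {
      run_end <- if (inside) i else i - 1L
      k <- run_end - run_start + 1L
      if (k / fs > min_dur_s) {
        onsets <- c(onsets, (run_start - 1L) / fs)
        offsets <- c(offsets, (run_start - 1L + k) / fs)
      }
      run_start <- NA_integer_
    }
  }
  data.frame(onset_s = onsets, offset_s = offsets,
             duration_s = offsets - onsets)
}

# A random 10-s trace at 250 Hz mixing burst-like and quiet stretches, for
# oracle-equivalence checks.
random_mixed_trace <- function(seed, fs = 250, dur_s = 10) {
  set.seed(seed)
  n <- dur_s * fs
  n_blocks <- sample(3:8, 1)
  edges <- sort(sample(2:(n - 1), n_blocks - 1))
  bounds <- c(0, edges, n)
  x <- numeric(n)
  for (b in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[b] + 1L):bounds[b + 1L]
    sd_b <- sample(c(2, 5, 10, 20, 40), 1)
    x[idx] <- rnorm(length(idx), sd = sd_b)
  }
  x
}

# A tiny cohort spec (3 subjects/group, short records) for fast pipeline and
# statistics tests.
small_cohort <- function(seed = 1L, n = 3L, dur = 400, a0 = 60, alen = 300) {
  mk <- function(group, emergence_mean_s, atp_mean, dct_mean) {
    list(label = group, n_subjects = n,
         bs_config = bs_preset(group, seed = 0L, duration_s = dur,
                               anesthesia_start_s = a0,
                               anesthesia_len_s = alen),
         phot_config = photometry_preset(group, seed = 0L, duration_s = dur,
                                         anesthesia_start_s = a0,
                                         anesthesia_len_s = alen),
         emergence_meanlog = log(emergence_mean_s), emergence_sdlog = 0.2,
         atp_mean = atp_mean, atp_sd = 0.8,
         dct_mean = dct_mean, dct_sd = 0.25)
  }
  cohort_spec(list(mk("young", 120, 10, 8.0), mk("aged", 300, 7, 9.0)),
              seed = seed)
}
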