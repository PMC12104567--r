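# Synthetic-cohort generator: alternating-renewal burst/suppression EEG,
# photometry traces with an anesthesia-locked decline, lognormal emergence
# times and scalar molecular measures, all seeded and with ground truth.

#' Burst-suppression EEG simulation configuration
#'
#' Defines a two-state (burst/suppression) alternating-renewal EEG inside an
#' anesthesia window, flanked by awake-like activity. State durations are
#' i.i.d. exponential or gamma with the given means; suppression samples are
#' zero-mean Gaussian noise, burst samples a band-weighted mixture of
#' band-limited noise rescaled to a target RMS. Raised-cosine amplitude ramps
#' at state changes are placed inside the non-suppression segments, so
#' suppression-labeled samples carry only suppression-state noise.
#'
#' @param seed Integer seed; the simulation is a pure function of the config.
#' @param duration_s Total record duration (s).
#' @param fs_hz Sampling rate, Hz (default 250).
#' @param anesthesia_start_s,anesthesia_end_s Anesthesia window (s), half-open.
#' @param mean_suppression_s,mean_burst_s Mean state durations (s).
#' @param duration_law `"exponential"` or `"gamma"` (shape `gamma_shape`).
#' @param gamma_shape Gamma shape k (default 2); ignored for exponential.
#' @param sigma_suppression_uv Suppression-state noise SD, uV (default 4;
#'   must stay below 5 so suppression samples sit within +/-15 uV with
#'   per-sample probability > 0.997).
#' @param burst_rms_uv Burst-state RMS, uV (default 40).
#' @param band_weights Named nonnegative weights for delta/theta/alpha/beta
#'   band-limited components; must sum to 1 (within 1e-9).
#' @param transition_ramp_s Raised-cosine ramp length at state changes (s,
#'   default 0.05).
#' @param pre_anesthesia_rms_uv RMS of the awake-like signal outside the
#'   anesthesia window (default 25).
#' @return A `bs_sim_config` list.
#' @export
bs_sim_config <- function(seed, duration_s, fs_hz = 250,
                          anesthesia_start_s, anesthesia_end_s,
                          mean_suppression_s, mean_burst_s,
                          duration_law = c("exponential", "gamma"),
                          gamma_shape = 2,
                          sigma_suppression_uv = 4,
                          burst_rms_uv = 40,
                          band_weights = c(delta = 0.45, theta = 0.25,
                                           alpha = 0.18, beta = 0.12),
                          transition_ramp_s = 0.05,
                          pre_anesthesia_rms_uv = 25) {
  duration_law <- match.arg(duration_law)
  chk <- function(cond, field, msg) {
    if (!cond) stop_config("invalid %s: %s", field, msg)
  }
  chk(is.numeric(seed) && length(seed) == 1L && is.finite(seed), "seed",
      "must be a single integer")
  chk(is.numeric(duration_s) && duration_s > 0, "duration_s", "must be > 0")
  chk(is.numeric(fs_hz) && fs_hz > 0, "fs_hz", "must be > 0")
  chk(anesthesia_start_s >= 0 && anesthesia_start_s < anesthesia_end_s,
      "anesthesia_start_s", "must satisfy 0 <= start < end")
  chk(anesthesia_end_s <= duration_s, "anesthesia_end_s",
      "must be <= duration_s")
  chk(mean_suppression_s > 0, "mean_suppression_s", "must be > 0")
  chk(mean_burst_s > 0, "mean_burst_s", "must be > 0")
  chk(gamma_shape > 0, "gamma_shape", "must be > 0")
  chk(sigma_suppression_uv > 0 && sigma_suppression_uv < 15 / 3,
      "sigma_suppression_uv", "must be in (0, 5) so suppression stays within +/-15 uV")
  chk(burst_rms_uv > 0, "burst_rms_uv", "must be > 0")
  chk(all(c("delta", "theta", "alpha", "beta") %in% names(band_weights)),
      "band_weights", "must name delta, theta, alpha, beta")
  chk(all(band_weights >= 0) && abs(sum(band_weights) - 1) <= 1e-9,
      "band_weights", "must be nonnegative and sum to 1 (within 1e-9)")
  chk(transition_ramp_s >= 0, "transition_ramp_s", "must be >= 0")
  chk(pre_anesthesia_rms_uv > 0, "pre_anesthesia_rms_uv", "must be > 0")
  structure(list(
    seed = as.integer(seed), duration_s = duration_s, fs_hz = fs_hz,
    anesthesia_start_s = anesthesia_start_s,
    anesthesia_end_s = anesthesia_end_s,
    mean_suppression_s = mean_suppression_s, mean_burst_s = mean_burst_s,
    duration_law = duration_law, gamma_shape = gamma_shape,
    sigma_suppression_uv = sigma_suppression_uv, burst_rms_uv = burst_rms_uv,
    band_weights = band_weights[c("delta", "theta", "alpha", "beta")],
    transition_ramp_s = transition_ramp_s,
    pre_anesthesia_rms_uv = pre_anesthesia_rms_uv
  ), class = "bs_sim_config")
}

#' Photometry simulation configuration
#'
#' Simulates F(t) = f0 * (1 - decline_fraction * s(t)) - bleach_slope * t +
#' noise, where s(t) = 1 - exp(-(t - onset)/tau) after `decline_onset_s` and
#' 0 before.
#'
#' @param seed Integer seed.
#' @param duration_s Duration (s).
#' @param fs_hz Sampling rate, Hz (default 100).
#' @param f0_au Baseline fluorescence (> 0, arbitrary units).
#' @param decline_fraction Fractional decline in `[0, 1)`; 0 for a flat trace.
#' @param decline_onset_s,decline_tau_s Onset and time constant of the
#'   saturating decline (s).
#' @param bleach_slope_au_per_s Linear photobleaching drift (a.u./s).
#' @param noise_sd_au Additive Gaussian noise SD (a.u.).
#' @param anesthesia_start_s,anesthesia_end_s Optional annotations carried to
#'   the trace (s).
#' @return A `photometry_sim_config` list.
#' @export
photometry_sim_config <- function(seed, duration_s, fs_hz = 100, f0_au = 100,
                                  decline_fraction = 0, decline_onset_s = 0,
                                  decline_tau_s = 60,
                                  bleach_slope_au_per_s = 0,
                                  noise_sd_au = 0,
                                  anesthesia_start_s = NULL,
                                  anesthesia_end_s = NULL) {
  chk <- function(cond, field, msg) {
    if (!cond) stop_config("invalid %s: %s", field, msg)
  }
  chk(is.numeric(seed) && length(seed) == 1L, "seed", "must be a single integer")
  chk(duration_s > 0, "duration_s", "must be > 0")
  chk(fs_hz > 0, "fs_hz", "must be > 0")
  chk(f0_au > 0, "f0_au", "must be > 0")
  chk(decline_fraction >= 0 && decline_fraction < 1, "decline_fraction",
      "must be in [0, 1)")
  chk(decline_tau_s > 0, "decline_tau_s", "must be > 0")
  chk(noise_sd_au >= 0, "noise_sd_au", "must be >= 0")
  structure(list(
    seed = as.integer(seed), duration_s = duration_s, fs_hz = fs_hz,
    f0_au = f0_au, decline_fraction = decline_fraction,
    decline_onset_s = decline_onset_s, decline_tau_s = decline_tau_s,
    bleach_slope_au_per_s = bleach_slope_au_per_s, noise_sd_au = noise_sd_au,
    anesthesia_start_s = anesthesia_start_s,
    anesthesia_end_s = anesthesia_end_s
  ), class = "photometry_sim_config")
}

# Draw one state duration.
draw_duration <- function(mean_s, law, shape) {
  if (law == "exponential") stats::rexp(1, rate = 1 / mean_s)
  else stats::rgamma(1, shape = shape, scale = mean_s / shape)
}

#' Simulate the burst/suppression state sequence only
#'
#' Draws the alternating-renewal state sequence of a [bs_sim_config()]
#' without synthesizing the waveform — useful for studying the sampling
#' distribution of the ground-truth burst suppression ratio cheaply.
#'
#' @param config A [bs_sim_config()].
#' @return A list with `states` (data.frame: state, start_s, end_s covering
#'   `[0, duration_s)`), `true_suppression_time_s` and `true_bsr_percent`
#'   (both over the anesthesia window).
#' @export
simulate_bs_states <- function(config) {
  if (!inherits(config, "bs_sim_config")) {
    stop_config("config must be a bs_sim_config")
  }
  with_seed(config$seed, simulate_bs_states_impl(config))
}

simulate_bs_states_impl <- function(config) {
  a0 <- config$anesthesia_start_s; a1 <- config$anesthesia_end_s
  segs <- list()
  if (a0 > 0) segs[[1]] <- c(0, a0, 1)          # 1 = awake
  t <- a0
  state <- "burst"                              # anesthesia opens with a burst
  while (t < a1) {
    mean_s <- if (state == "burst") config$mean_burst_s else config$mean_suppression_s
    d <- draw_duration(mean_s, config$duration_law, config$gamma_shape)
    end <- min(t + d, a1)
    segs[[length(segs) + 1L]] <- c(t, end, if (state == "burst") 2 else 3)
    t <- end
    state <- if (state == "burst") "suppression" else "burst"
  }
  if (a1 < config$duration_s) {
    segs[[length(segs) + 1L]] <- c(a1, config$duration_s, 1)
  }
  m <- do.call(rbind, segs)
  states <- data.frame(
    state = c("awake", "burst", "suppression")[m[, 3]],
    start_s = m[, 1], end_s = m[, 2], stringsAsFactors = FALSE)
  supp <- states$state == "suppression"
  supp_time <- sum(pmin(states$end_s[supp], a1) - pmax(states$start_s[supp], a0))
  list(states = states,
       true_suppression_time_s = supp_time,
       true_bsr_percent = 100 * supp_time / (a1 - a0))
}

# Unit-RMS band-weighted noise of length n: white noise filtered into the
# four canonical bands, each normalized to unit RMS, combined with
# sqrt(weight) so band power fractions match the weights.
band_weighted_noise <- function(n, fs, weights, bands = default_bands()) {
  out <- numeric(n)
  nyq <- fs / 2
  for (b in names(weights)) {
    w <- weights[[b]]
    if (w <= 0) next
    edges <- pmin(bands[[b]], nyq * 0.99) / nyq
    bf <- signal::butter(4, edges, type = "pass")
    z <- signal::filtfilt(bf, stats::rnorm(n))
    out <- out + sqrt(w) * z / rms(z)
  }
  out / rms(out)
}

# Per-sample state codes (1 awake, 2 burst, 3 suppression) for sample start
# times (i-1)/fs falling in each half-open segment.
states_to_labels <- function(states, n, fs) {
  t <- (seq_len(n) - 1L) / fs
  idx <- findInterval(t, states$start_s)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(states)] <- nrow(states)
  states$state[idx]
}

#' Simulate a burst-suppression EEG recording with ground truth
#'
#' @param config A [bs_sim_config()].
#' @return A list with `recording` (an [eeg_recording()] annotated with the
#'   anesthesia window) and `ground_truth`: per-sample `state_labels`
#'   (`awake`/`burst`/`suppression`), `true_bsr_percent`,
#'   `true_suppression_time_s`, and the `states` segment table.
#' @export
simulate_bs_eeg <- function(config) {
  if (!inherits(config, "bs_sim_config")) {
    stop_config("config must be a bs_sim_config")
  }
  with_seed(config$seed, {
    st <- simulate_bs_states_impl(config)
    states <- st$states
    fs <- config$fs_hz
    n <- round(config$duration_s * fs)

    # target amplitude per sample: awake/burst RMS, 0 in suppression
    amp_of <- c(awake = config$pre_anesthesia_rms_uv,
                burst = config$burst_rms_uv, suppression = 0)
    labels <- states_to_labels(states, n, fs)
    amp <- unname(amp_of[labels])

    # raised-cosine tapers inside non-suppression segments at edges that
    # adjoin suppression, so suppression samples stay pure noise
    ramp_n <- round(config$transition_ramp_s * fs)
    if (ramp_n > 0L) {
      r <- rle(labels != "suppression")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        i0 <- starts[k]; i1 <- ends[k]
        len <- i1 - i0 + 1L
        h <- min(ramp_n, len %/% 2L)
        if (h < 1L) next
        up <- 0.5 * (1 - cos(pi * (seq_len(h)) / (h + 1)))
        if (i0 > 1L) amp[i0:(i0 + h - 1L)] <- amp[i0:(i0 + h - 1L)] * up
        if (i1 < n) amp[(i1 - h + 1L):i1] <- amp[(i1 - h + 1L):i1] * rev(up)
      }
    }

    carrier <- band_weighted_noise(n, fs, config$band_weights)
    x <- amp * carrier + stats::rnorm(n, sd = config$sigma_suppression_uv)

    rec <- eeg_recording(x, fs,
                         anesthesia_start_s = config$anesthesia_start_s,
                         anesthesia_end_s = config$anesthesia_end_s)
    list(recording = rec,
         ground_truth = list(state_labels = labels,
                             true_bsr_percent = st$true_bsr_percent,
                             true_suppression_time_s = st$true_suppression_time_s,
                             states = states))
  })
}

#' Simulate a fiber-photometry trace with ground truth
#'
#' @param config A [photometry_sim_config()].
#' @return A list with `trace` (a [photometry_trace()]) and `ground_truth`
#'   (`true_decline_fraction`, the noiseless trace `f_clean`).
#' @export
simulate_photometry <- function(config) {
  if (!inherits(config, "photometry_sim_config")) {
    stop_config("config must be a photometry_sim_config")
  }
  with_seed(config$seed, {
    n <- round(config$duration_s * config$fs_hz)
    t <- (seq_len(n) - 1L) / config$fs_hz
    s <- ifelse(t > config$decline_onset_s,
                1 - exp(-(t - config$decline_onset_s) / config$decline_tau_s), 0)
    f_clean <- config$f0_au * (1 - config$decline_fraction * s) -
      config$bleach_slope_au_per_s * t
    f <- f_clean
    if (config$noise_sd_au > 0) f <- f + stats::rnorm(n, sd = config$noise_sd_au)
    trace <- photometry_trace(f, config$fs_hz,
                              anesthesia_start_s = config$anesthesia_start_s,
                              anesthesia_end_s = config$anesthesia_end_s)
    list(trace = trace,
         ground_truth = list(true_decline_fraction = config$decline_fraction,
                             f_clean = f_clean))
  })
}

# ---------------------------------------------------------------------------
# Cohort presets and the cohort writer.

#' Preset burst-suppression configurations for young and aged cohorts
#'
#' The aged preset targets a 60% burst suppression ratio (mean suppression
#' 6 s, mean burst 4 s, gamma(k=2) durations) with a delta-dominated band
#' mix; the young preset targets 20% (4 s / 16 s) with a flatter band mix.
#' Gamma(k=2) durations keep the 20-min ground-truth BSR within about two
#' percentage points (SD) of the target.
#'
#' @param group `"aged"` or `"young"`.
#' @param seed Integer seed.
#' @param duration_s Total record length (default 1500 s).
#' @param anesthesia_start_s Anesthesia onset (default 180 s).
#' @param anesthesia_len_s Anesthesia length (default 1200 s = 20 min).
#' @return A [bs_sim_config()].
#' @export
bs_preset <- function(group = c("aged", "young"), seed = 1L,
                      duration_s = 1500, anesthesia_start_s = 180,
                      anesthesia_len_s = 1200) {
  group <- match.arg(group)
  if (group == "aged") {
    bs_sim_config(seed = seed, duration_s = duration_s,
                  anesthesia_start_s = anesthesia_start_s,
                  anesthesia_end_s = anesthesia_start_s + anesthesia_len_s,
                  mean_suppression_s = 6, mean_burst_s = 4,
                  duration_law = "gamma", gamma_shape = 2,
                  band_weights = c(delta = 0.60, theta = 0.20,
                                   alpha = 0.12, beta = 0.08))
  } else {
    bs_sim_config(seed = seed, duration_s = duration_s,
                  anesthesia_start_s = anesthesia_start_s,
                  anesthesia_end_s = anesthesia_start_s + anesthesia_len_s,
                  mean_suppression_s = 4, mean_burst_s = 16,
                  duration_law = "gamma", gamma_shape = 2,
                  band_weights = c(delta = 0.30, theta = 0.25,
                                   alpha = 0.25, beta = 0.20))
  }
}

#' Preset photometry configurations for young and aged cohorts
#'
#' Young: flat ATP signal (no decline). Aged: 20% saturating decline locked
#' to anesthesia onset (tau 60 s). Both include mild noise and bleaching.
#'
#' @inheritParams bs_preset
#' @return A [photometry_sim_config()].
#' @export
photometry_preset <- function(group = c("aged", "young"), seed = 1L,
                              duration_s = 1500, anesthesia_start_s = 180,
                              anesthesia_len_s = 1200) {
  group <- match.arg(group)
  photometry_sim_config(
    seed = seed, duration_s = duration_s, fs_hz = 100, f0_au = 100,
    decline_fraction = if (group == "aged") 0.2 else 0,
    decline_onset_s = anesthesia_start_s, decline_tau_s = 60,
    bleach_slope_au_per_s = 0.002, noise_sd_au = 1,
    anesthesia_start_s = anesthesia_start_s,
    anesthesia_end_s = anesthesia_start_s + anesthesia_len_s)
}

#' Specify a synthetic cohort
#'
#' @param groups A list of group descriptors, each a list with fields
#'   `label`, `n_subjects`, `bs_config` (a [bs_sim_config()] used as the
#'   per-subject template), `phot_config` (a [photometry_sim_config()]
#'   template), `emergence_meanlog`, `emergence_sdlog` (lognormal
#'   righting-reflex recovery times, seconds), and optional scalar-measure
#'   parameters `atp_mean`, `atp_sd` (tissue ATP, nmol/mg),
#'   `dct_mean`, `dct_sd` (qPCR delta-Ct target minus reference).
#' @param seed Master cohort seed; per-subject seeds are
#'   `seed + 1000 * group_index + subject_index` and are recorded in the
#'   manifest.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(groups, seed = 1L) {
  labels <- vapply(groups, function(g) g$label, character(1))
  if (anyDuplicated(labels)) stop_config("group labels must be unique")
  for (g in groups) {
    if (is.null(g$n_subjects) || g$n_subjects < 1) {
      stop_config("invalid n_subjects for group '%s'", g$label)
    }
    if (!inherits(g$bs_config, "bs_sim_config")) {
      stop_config("group '%s' needs a bs_sim_config", g$label)
    }
    if (!inherits(g$phot_config, "photometry_sim_config")) {
      stop_config("group '%s' needs a photometry_sim_config", g$label)
    }
  }
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' A ready-made aged-vs-young demonstration cohort
#'
#' @param seed Master seed.
#' @param n_per_group Subjects per group (default 4, as in the study's
#'   baseline cohort).
#' @param duration_s,anesthesia_start_s,anesthesia_len_s Recording layout,
#'   passed to the presets.
#' @return A [cohort_spec()].
#' @export
cohort_preset_aging <- function(seed = 1L, n_per_group = 4L,
                                duration_s = 1500, anesthesia_start_s = 180,
                                anesthesia_len_s = 1200) {
  mk <- function(group, emergence_mean_s, atp_mean, dct_mean) {
    list(label = group, n_subjects = n_per_group,
         bs_config = bs_preset(group, seed = 0L, duration_s = duration_s,
                               anesthesia_start_s = anesthesia_start_s,
                               anesthesia_len_s = anesthesia_len_s),
         phot_config = photometry_preset(group, seed = 0L,
                                         duration_s = duration_s,
                                         anesthesia_start_s = anesthesia_start_s,
                                         anesthesia_len_s = anesthesia_len_s),
         emergence_meanlog = log(emergence_mean_s), emergence_sdlog = 0.2,
         atp_mean = atp_mean, atp_sd = 0.8,
         dct_mean = dct_mean, dct_sd = 0.25)
  }
  # aged mice: slower emergence, lower tissue ATP, lower NDUFA10 expression
  cohort_spec(list(mk("young", 120, 10, 8.0),
                   mk("aged", 300, 7, 9.0)), seed = seed)
}

#' Simulate and write a full synthetic cohort to disk
#'
#' Writes, per subject, an EEG file (TSV or EDF) with sidecar annotations, a
#' photometry TSV, and a ground-truth JSON (run-length-encoded per-sample
#' state labels, true BSR and suppression time); plus cohort-level
#' `emergence.tsv`, `atp.tsv`, `qpcr.tsv` tables and a `manifest.json`
#' listing every file, seed and preset. Re-running with the same spec
#' reproduces identical files.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @param format `"tsv"` (default) or `"edf"` for the EEG traces.
#' @return The manifest, invisibly (also written as JSON).
#' @export
simulate_cohort <- function(spec, out_dir, format = c("tsv", "edf")) {
  if (!inherits(spec, "cohort_spec")) stop_config("spec must be a cohort_spec")
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_io("cannot create output directory %s", out_dir)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("output directory %s is not writable", out_dir)
  unlink(probe)

  manifest <- list(seed = spec$seed, format = format, groups = list(),
                   files = character(0))
  emergence <- list(); atp <- list(); qpcr <- list()

  for (gi in seq_along(spec$groups)) {
    g <- spec$groups[[gi]]
    subj_entries <- list()
    for (si in seq_len(g$n_subjects)) {
      subj_seed <- spec$seed + 1000L * gi + si
      sid <- sprintf("%s_%02d", g$label, si)

      bs_cfg <- g$bs_config; bs_cfg$seed <- subj_seed
      sim <- simulate_bs_eeg(bs_cfg)
      rec <- sim$recording
      rec$subject_id <- sid; rec$group_label <- g$label
      eeg_file <- file.path(out_dir, sprintf("%s_eeg.%s", sid, format))
      write_eeg(rec, eeg_file, format = format)

      ph_cfg <- g$phot_config; ph_cfg$seed <- subj_seed + 500000L
      phot <- simulate_photometry(ph_cfg)
      tr <- phot$trace; tr$subject_id <- sid; tr$group_label <- g$label
      phot_file <- file.path(out_dir, sprintf("%s_photometry.tsv", sid))
      write_photometry(tr, phot_file)

      gt <- sim$ground_truth
      r <- rle(gt$state_labels)
      gt_file <- file.path(out_dir, sprintf("%s_ground_truth.json", sid))
      jsonlite::write_json(list(
        subject_id = sid, group_label = g$label,
        true_bsr_percent = gt$true_bsr_percent,
        true_suppression_time_s = gt$true_suppression_time_s,
        photometry_true_decline = ph_cfg$decline_fraction,
        state_rle = list(lengths = r$lengths, values = r$values)
      ), gt_file, auto_unbox = TRUE, digits = NA)

      manifest$files <- c(manifest$files,
                          basename(eeg_file), basename(sidecar_path(eeg_file)),
                          basename(phot_file), basename(sidecar_path(phot_file)),
                          basename(gt_file))
      subj_entries[[si]] <- list(subject_id = sid, seed = subj_seed,
                                 eeg = basename(eeg_file),
                                 photometry = basename(phot_file),
                                 ground_truth = basename(gt_file))

      em_seed <- subj_seed + 900000L
      emergence[[length(emergence) + 1L]] <- data.frame(
        subject_id = sid, group_label = g$label,
        rrr_time_s = with_seed(em_seed, stats::rlnorm(
          1, meanlog = g$emergence_meanlog, sdlog = g$emergence_sdlog)))
      if (!is.null(g$atp_mean)) {
        atp[[length(atp) + 1L]] <- data.frame(
          subject_id = sid, group_label = g$label,
          atp_nmol_per_mg = with_seed(em_seed + 1L, stats::rnorm(
            1, g$atp_mean, g$atp_sd)))
      }
      if (!is.null(g$dct_mean)) {
        qpcr[[length(qpcr) + 1L]] <- with_seed(em_seed + 2L, {
          ct_ref <- stats::rnorm(1, 18, 0.3)
          data.frame(subject_id = sid, group_label = g$label,
                     ct_target = ct_ref + stats::rnorm(1, g$dct_mean, g$dct_sd),
                     ct_reference = ct_ref)
        })
      }
    }
    manifest$groups[[gi]] <- list(
      label = g$label, n_subjects = g$n_subjects,
      target_bsr_percent = 100 * g$bs_config$mean_suppression_s /
        (g$bs_config$mean_suppression_s + g$bs_config$mean_burst_s),
      duration_law = g$bs_config$duration_law,
      decline_fraction = g$phot_config$decline_fraction,
      subjects = subj_entries)
  }

  write_tbl <- function(lst, name) {
    if (!length(lst)) return(NULL)
    df <- do.call(rbind, lst)
    f <- file.path(out_dir, name)
    utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$files <<- c(manifest$files, name)
    f
  }
  write_tbl(emergence, "emergence.tsv")
  write_tbl(atp, "atp.tsv")
  write_tbl(qpcr, "qpcr.tsv")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
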