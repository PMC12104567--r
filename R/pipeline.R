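# End-to-end pipeline: simulate (or load) a cohort, filter, detect
# suppressions, compute band power and dF/F, assemble measures, run the
# group statistics, and write a reproducible report bundle.

#' Build a pipeline run configuration
#'
#' Defaults mirror the study's printed recording parameters: 250 Hz EEG
#' sampling, 0.5-70 Hz band, +/-15 uV / > 0.2 s suppression rule, 100-s
#' dF/F baseline, 20-min anesthesia window.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed; all per-subject seeds derive from it.
#' @param cohort A [cohort_spec()], or `NULL` to use
#'   [cohort_preset_aging()] with `n_per_group`.
#' @param n_per_group Subjects per group for the default cohort (default 4).
#' @param eeg_format `"tsv"` or `"edf"` for simulated EEG files.
#' @param threshold_uv,min_duration_s Suppression-detection parameters.
#' @param filter_low_hz,filter_high_hz Recording band edges (Hz).
#' @param baseline_len_s dF/F baseline length (s).
#' @param seg_s,overlap Welch parameters for band power.
#' @return A `bsr_run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, cohort = NULL, n_per_group = 4L,
                       eeg_format = "tsv", threshold_uv = 15,
                       min_duration_s = 0.2, filter_low_hz = 0.5,
                       filter_high_hz = 70, baseline_len_s = 100,
                       seg_s = 2, overlap = 0.5) {
  if (is.null(cohort)) {
    cohort <- cohort_preset_aging(seed = seed, n_per_group = n_per_group)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 eeg_format = eeg_format, threshold_uv = threshold_uv,
                 min_duration_s = min_duration_s,
                 filter_low_hz = filter_low_hz,
                 filter_high_hz = filter_high_hz,
                 baseline_len_s = baseline_len_s,
                 seg_s = seg_s, overlap = overlap),
            class = "bsr_run_config")
}

#' Validate a pipeline configuration
#'
#' Checks every module precondition reachable from the configuration and
#' returns one finding per violation, each naming the offending field path.
#' An empty result means the configuration is runnable.
#'
#' @param config A `bsr_run_config` (or a plain list with the same fields).
#' @return Character vector of findings (empty iff valid).
#' @export
validate_config <- function(config) {
  findings <- character(0)
  add <- function(path, msg) findings <<- c(findings, sprintf("%s: %s", path, msg))
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  if (!num1(config$threshold_uv) || config$threshold_uv <= 0) {
    add("detection.threshold_uv", "must be a single number > 0")
  }
  if (!num1(config$min_duration_s) || config$min_duration_s < 0) {
    add("detection.min_duration_s", "must be a single number >= 0")
  }
  if (!num1(config$filter_low_hz) || !num1(config$filter_high_hz) ||
      config$filter_low_hz <= 0 ||
      config$filter_low_hz >= config$filter_high_hz) {
    add("filter", "must satisfy 0 < filter_low_hz < filter_high_hz")
  }
  if (!num1(config$baseline_len_s) || config$baseline_len_s <= 0) {
    add("photometry.baseline_len_s", "must be > 0")
  }
  if (!num1(config$seg_s) || config$seg_s <= 0) add("spectral.seg_s", "must be > 0")
  if (!num1(config$overlap) || config$overlap < 0 || config$overlap >= 1) {
    add("spectral.overlap", "must be in [0, 1)")
  }
  if (!inherits(config$cohort, "cohort_spec")) {
    add("cohort", "must be a cohort_spec")
  } else {
    for (gi in seq_along(config$cohort$groups)) {
      g <- config$cohort$groups[[gi]]
      bc <- g$bs_config
      pfx <- sprintf("cohort.groups[%d]", gi)
      if (bc$anesthesia_end_s <= bc$anesthesia_start_s) {
        add(paste0(pfx, ".bs_config.anesthesia_end_s"),
            "anesthesia_end_s must exceed anesthesia_start_s")
      }
      if (num1(config$filter_high_hz) && config$filter_high_hz >= bc$fs_hz / 2) {
        add("filter.filter_high_hz",
            sprintf("must be below fs/2 = %g Hz", bc$fs_hz / 2))
      }
      if (bc$anesthesia_start_s < config$baseline_len_s &&
          g$phot_config$decline_fraction >= 0) {
        # baseline is clipped at record start; informational only when the
        # pre-anesthesia segment is shorter than the requested baseline
        if (bc$anesthesia_start_s <= 0) {
          add(paste0(pfx, ".bs_config.anesthesia_start_s"),
              "no pre-anesthesia segment for the dF/F baseline")
        }
      }
    }
  }
  findings
}

stage <- function(name, log_con, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage=%s status=failed error=%s", name,
                       conditionMessage(e)), log_con)
    bsr_stop("pipeline stage '%s' failed: %s", "bsr_stage_error",
             name, conditionMessage(e))
  })
  writeLines(sprintf("stage=%s status=ok elapsed_s=%.2f", name,
                     proc.time()[["elapsed"]] - t0), log_con)
  res
}

#' Run the full analysis pipeline
#'
#' Simulates the configured cohort to disk, reads every trace back through
#' the file layer, applies the recording-band filter, detects suppression
#' events, computes per-subject suppression summaries, band-power tables and
#' dF/F epoch changes, assembles the long measures table (suppression time,
#' BSR, four band fractions, emergence time, photometry change, tissue ATP,
#' relative expression) and runs the group statistics. All numeric outputs
#' are deterministic functions of the configuration and master seed.
#'
#' @param config A `bsr_run_config` from [run_config()].
#' @return Invisibly, a list with `manifest`, `measures`, `stats`, and the
#'   output paths. Outputs on disk: the cohort files under `cohort/`,
#'   per-subject event TSVs under `events/`, `summaries.tsv`,
#'   `bandpower.tsv`, `dff_changes.tsv`, per-group mean dF/F traces,
#'   `measures.tsv`, `stats.tsv`, `run_manifest.json`, and `run_log.txt`
#'   (the log holds timings and is the only non-deterministic file).
#' @export
run_pipeline <- function(config) {
  findings <- validate_config(config)
  if (length(findings)) {
    stop_config("invalid configuration:\n  %s", paste(findings, collapse = "\n  "))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run_log.txt"), "w")
  on.exit(close(log_con))

  cohort_dir <- file.path(out_dir, "cohort")
  manifest <- stage("simulate", log_con,
                    simulate_cohort(config$cohort, cohort_dir,
                                    format = config$eeg_format))

  events_dir <- file.path(out_dir, "events")
  dir.create(events_dir, showWarnings = FALSE)

  summaries <- list(); bandpower <- list(); dff_changes <- list()
  measures <- list()
  add_measure <- function(sid, grp, name, value) {
    measures[[length(measures) + 1L]] <<- data.frame(
      subject_id = sid, group_label = grp, measure = name, value = value)
  }
  dffs_by_group <- list()

  stage("analyze_subjects", log_con, {
    for (grp in manifest$groups) {
      for (subj in grp$subjects) {
        sid <- subj$subject_id
        rec <- read_eeg(file.path(cohort_dir, subj$eeg))
        filt <- bandpass_filter(rec, config$filter_low_hz, config$filter_high_hz)
        events <- detect_suppressions(filt, config$threshold_uv,
                                      config$min_duration_s, filter = FALSE)
        win <- anesthesia_window(rec)
        tot <- cumulative_suppression_time(events, win)
        bsr <- bsr_global(events, win)
        write_events_tsv(events, file.path(events_dir, paste0(sid, "_events.tsv")),
                         subject_id = sid)
        summaries[[sid]] <- data.frame(
          subject_id = sid, group_label = grp$label,
          window_start_s = win[1], window_end_s = win[2],
          total_suppression_time_s = tot, bsr_percent = bsr,
          n_events = sum(events$offset_s > win[1] & events$onset_s < win[2]))
        add_measure(sid, grp$label, "suppression_time_s", tot)
        add_measure(sid, grp$label, "bsr_percent", bsr)

        bp <- relative_band_power(filt, window = win,
                                  seg_s = config$seg_s,
                                  overlap = config$overlap)
        for (k in seq_len(nrow(bp))) {
          add_measure(sid, grp$label, paste0(bp$band[k], "_rel_power"),
                      bp$rel_power[k])
        }
        bandpower[[sid]] <- data.frame(subject_id = sid,
                                        group_label = grp$label,
                                        band = bp$band,
                                        rel_power = bp$rel_power)

        tr <- read_photometry(file.path(cohort_dir, subj$photometry))
        dff <- compute_dff(tr, baseline_len_s = config$baseline_len_s)
        ch <- epoch_change(dff)
        dff_changes[[sid]] <- data.frame(
          subject_id = sid, group_label = grp$label,
          pre_mean = ch$pre_mean, during_mean = ch$during_mean,
          change = ch$change)
        add_measure(sid, grp$label, "dff_change", ch$change)
        dffs_by_group[[grp$label]] <- c(dffs_by_group[[grp$label]], list(dff))
      }
    }
  })

  stage("tables", log_con, {
    emergence <- read_measure_table(file.path(cohort_dir, "emergence.tsv"),
                                    c("subject_id", "group_label", "rrr_time_s"))
    for (k in seq_len(nrow(emergence))) {
      add_measure(emergence$subject_id[k], emergence$group_label[k],
                  "emergence_time_s", as.numeric(emergence$rrr_time_s[k]))
    }
    atp_path <- file.path(cohort_dir, "atp.tsv")
    if (file.exists(atp_path)) {
      atp <- read_measure_table(atp_path,
                                c("subject_id", "group_label", "atp_nmol_per_mg"))
      for (k in seq_len(nrow(atp))) {
        add_measure(atp$subject_id[k], atp$group_label[k], "atp_nmol_per_mg",
                    as.numeric(atp$atp_nmol_per_mg[k]))
      }
    }
    qpcr_path <- file.path(cohort_dir, "qpcr.tsv")
    if (file.exists(qpcr_path)) {
      qpcr <- read_measure_table(qpcr_path,
                                 c("subject_id", "group_label",
                                   "ct_target", "ct_reference"))
      qpcr$ct_target <- as.numeric(qpcr$ct_target)
      qpcr$ct_reference <- as.numeric(qpcr$ct_reference)
      ctrl <- manifest$groups[[1]]$label
      expr <- ddct_relative_expression(qpcr, control_group = ctrl)
      for (k in seq_len(nrow(expr))) {
        add_measure(expr$subject_id[k], expr$group_label[k], "rel_expression",
                    expr$rel_expression[k])
      }
    }
  })

  measures_df <- do.call(rbind, measures)
  stats_tbl <- stage("stats", log_con, figure_table(measures_df))

  stage("write_outputs", log_con, {
    wt <- function(df, name) {
      utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                         file.path(out_dir, name), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    wt(do.call(rbind, c(summaries, list(make.row.names = FALSE))), "summaries.tsv")
    wt(do.call(rbind, c(bandpower, list(make.row.names = FALSE))), "bandpower.tsv")
    wt(do.call(rbind, c(dff_changes, list(make.row.names = FALSE))), "dff_changes.tsv")
    wt(measures_df, "measures.tsv")
    wt(stats_tbl$summary, "stats.tsv")
    for (grp in names(dffs_by_group)) {
      if (length(dffs_by_group[[grp]]) >= 2L) {
        gm <- group_mean_trace(dffs_by_group[[grp]])
        wt(gm, sprintf("dff_group_mean_%s.tsv", grp))
      }
    }
    cfg_json <- file.path(out_dir, "config.json")
    cfg_export <- config
    cfg_export$cohort <- NULL
    cfg_export$out_dir <- NULL       # paths stay out of the hashed config
    jsonlite::write_json(
      list(parameters = cfg_export, cohort_seed = config$cohort$seed,
           n_groups = length(config$cohort$groups)),
      cfg_json, auto_unbox = TRUE, digits = NA, force = TRUE)
    run_manifest <- list(
      package_version = as.character(utils::packageVersion("bsrtools")),
      master_seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_json)),
      cohort_manifest = manifest,
      outputs = c("summaries.tsv", "bandpower.tsv", "dff_changes.tsv",
                  "measures.tsv", "stats.tsv",
                  sprintf("dff_group_mean_%s.tsv",
                          names(dffs_by_group)[vapply(dffs_by_group, length,
                                                      integer(1)) >= 2L]),
                  "config.json"))
    jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(list(manifest = manifest, measures = measures_df,
                 stats = stats_tbl, out_dir = out_dir))
}
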