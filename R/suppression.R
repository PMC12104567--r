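# Suppression-event detection and burst-suppression-ratio metrics.
#
# A suppression event is a maximal run of samples whose absolute amplitude
# stays within a threshold (inclusive, default +/-15 uV) for strictly longer
# than a minimum duration (default 0.2 s). A run of k samples spans k/fs
# seconds; events are half-open [onset_s, offset_s) intervals.

#' Detect suppression events by the amplitude-duration rule
#'
#' By default the recording is first band-pass filtered to the 0.5-70 Hz
#' recording band (see [bandpass_filter()]); set `filter = FALSE` to detect
#' on the raw samples. Runs touching the start or end of the record are kept
#' (their observed duration is a lower bound on the true one).
#'
#' @param rec An [eeg_recording()].
#' @param threshold_uv Amplitude threshold in uV; a sample is suppressed when
#'   `|x| <= threshold_uv` (inclusive, default 15).
#' @param min_duration_s Minimum event duration in seconds; runs are kept
#'   only when strictly longer (default 0.2).
#' @param filter Apply the 0.5-70 Hz zero-phase band-pass before detection
#'   (default `TRUE`).
#' @return A `suppression_events` data.frame with columns `onset_s`,
#'   `offset_s`, `duration_s`, sorted and non-overlapping.
#' @export
detect_suppressions <- function(rec, threshold_uv = 15, min_duration_s = 0.2,
                                filter = TRUE) {
  if (!inherits(rec, "eeg_recording")) stop_validation("rec must be an eeg_recording")
  if (length(rec$samples) == 0L) stop_validation("recording is empty")
  if (!is.numeric(threshold_uv) || threshold_uv <= 0) {
    stop_parameter("threshold_uv must be > 0")
  }
  if (!is.numeric(min_duration_s) || min_duration_s < 0) {
    stop_parameter("min_duration_s must be >= 0")
  }
  x <- if (filter) bandpass_filter(rec)$samples else rec$samples
  fs <- rec$fs_hz
  mask <- abs(x) <= threshold_uv
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fs > min_duration_s)
  ev <- data.frame(onset_s = (starts[keep] - 1L) / fs,
                   offset_s = ends[keep] / fs)
  ev$duration_s <- ev$offset_s - ev$onset_s
  class(ev) <- c("suppression_events", "data.frame")
  attr(ev, "threshold_uv") <- threshold_uv
  attr(ev, "min_duration_s") <- min_duration_s
  attr(ev, "fs_hz") <- fs
  ev
}

#' @export
print.suppression_events <- function(x, ...) {
  cat(sprintf("<suppression_events> %d events (threshold %g uV, > %g s)\n",
              nrow(x), attr(x, "threshold_uv") %||% NA,
              attr(x, "min_duration_s") %||% NA))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_events <- function(events) {
  if (!is.data.frame(events) ||
      !all(c("onset_s", "offset_s") %in% names(events))) {
    stop_validation("events must be a data.frame with onset_s and offset_s")
  }
  if (nrow(events) == 0L) return(invisible(events))
  if (any(events$offset_s <= events$onset_s)) {
    stop_validation("events must have offset_s > onset_s")
  }
  if (is.unsorted(events$onset_s, strictly = FALSE)) {
    stop_validation("events must be sorted by onset_s")
  }
  if (nrow(events) > 1L &&
      any(events$onset_s[-1L] < events$offset_s[-nrow(events)])) {
    stop_validation("events must be non-overlapping")
  }
  invisible(events)
}

#' Cumulative suppression time within a window
#'
#' Sums the lengths of the intersections of each event with the half-open
#' analysis window; events straddling a window edge contribute only the
#' intersected part. The default window in downstream summaries is the
#' anesthesia window (onset to cessation).
#'
#' @param events A sorted, non-overlapping event table (see
#'   [detect_suppressions()]).
#' @param window Numeric `c(start_s, end_s)`, half-open.
#' @return Total suppression time in seconds.
#' @export
cumulative_suppression_time <- function(events, window) {
  check_events(events)
  check_window(window)
  if (nrow(events) == 0L) return(0)
  lo <- pmax(events$onset_s, window[1])
  hi <- pmin(events$offset_s, window[2])
  sum(pmax(hi - lo, 0))
}

#' Global burst suppression ratio
#'
#' `100 * cumulative_suppression_time / window length`, in percent.
#'
#' @inheritParams cumulative_suppression_time
#' @return BSR in percent, in `[0, 100]`.
#' @export
bsr_global <- function(events, window) {
  check_window(window)
  len <- window[2] - window[1]
  if (len <= 0) stop_parameter("window length must be > 0")
  100 * cumulative_suppression_time(events, window) / len
}

#' Windowed burst-suppression-ratio time course
#'
#' Evaluates [bsr_global()] on sliding half-open windows covering the
#' anesthesia interval; a partial trailing window is dropped.
#'
#' @param rec An [eeg_recording()] carrying anesthesia annotations (or pass
#'   `window`).
#' @param events Event table from [detect_suppressions()].
#' @param win_s Window length (s, default 60).
#' @param step_s Step between window starts (s, default 10).
#' @param window Optional analysis window overriding the annotations.
#' @return A `bsr_timecourse` data.frame with `window_start_s`,
#'   `window_center_s`, `bsr_percent`; attributes `win_s`, `step_s`.
#' @export
bsr_timecourse <- function(rec, events, win_s = 60, step_s = 10,
                           window = NULL) {
  if (win_s <= 0 || step_s <= 0) stop_parameter("win_s and step_s must be > 0")
  if (is.null(window)) window <- anesthesia_window(rec)
  check_window(window)
  if (win_s > window[2] - window[1]) {
    stop_parameter("win_s (%g) exceeds the analysis window length (%g)",
                   win_s, window[2] - window[1])
  }
  starts <- seq(window[1], window[2] - win_s, by = step_s)
  bsr <- vapply(starts, function(s0) bsr_global(events, c(s0, s0 + win_s)),
                numeric(1))
  out <- data.frame(window_start_s = starts,
                    window_center_s = starts + win_s / 2,
                    bsr_percent = bsr)
  class(out) <- c("bsr_timecourse", "data.frame")
  attr(out, "win_s") <- win_s
  attr(out, "step_s") <- step_s
  out
}

#' Per-recording suppression summary
#'
#' Detects events and aggregates cumulative suppression time, global BSR and
#' event count over the analysis window (default: the recording's anesthesia
#' window, i.e. anesthesia onset to cessation).
#'
#' @inheritParams detect_suppressions
#' @param window Optional analysis window `c(start_s, end_s)`; defaults to
#'   the anesthesia annotations.
#' @return A `suppression_summary` list: `window`,
#'   `total_suppression_time_s`, `bsr_percent`, `n_events`, `events`.
#' @export
suppression_summary <- function(rec, threshold_uv = 15, min_duration_s = 0.2,
                                filter = TRUE, window = NULL) {
  events <- detect_suppressions(rec, threshold_uv, min_duration_s, filter)
  if (is.null(window)) window <- anesthesia_window(rec)
  check_window(window)
  tot <- cumulative_suppression_time(events, window)
  in_win <- events$offset_s > window[1] & events$onset_s < window[2]
  structure(list(
    subject_id = rec$subject_id, group_label = rec$group_label,
    window = window, total_suppression_time_s = tot,
    bsr_percent = 100 * tot / (window[2] - window[1]),
    n_events = sum(in_win), events = events
  ), class = "suppression_summary")
}

#' @export
print.suppression_summary <- function(x, ...) {
  cat(sprintf(paste0("<suppression_summary> %s window [%g, %g) s: ",
                     "%d events, %.1f s suppressed, BSR %.1f%%\n"),
              if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
              x$window[1], x$window[2], x$n_events,
              x$total_suppression_time_s, x$bsr_percent))
  invisible(x)
}

#' Write detected events to TSV
#'
#' Columns `subject_id`, `onset_s`, `offset_s`, `duration_s` (6 decimals).
#'
#' @param events Event table.
#' @param path Output path.
#' @param subject_id Subject id column value.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path, subject_id = "") {
  check_events(events)
  df <- data.frame(subject_id = rep(subject_id, nrow(events)),
                   onset_s = sprintf("%.6f", events$onset_s),
                   offset_s = sprintf("%.6f", events$offset_s),
                   duration_s = sprintf("%.6f", events$duration_s))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
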