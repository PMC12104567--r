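# Fiber-photometry delta-F/F computation and pre/during-anesthesia
# quantification.

#' Compute delta-F/F from a photometry trace
#'
#' dF/F is `(F - F0) / F0` with `F0` the mean fluorescence over a baseline
#' control window; by default the 100 s immediately preceding anesthesia
#' onset. dF/F is invariant to rescaling F by any positive constant.
#'
#' @param trace A [photometry_trace()].
#' @param baseline_window `c(start_s, end_s)`; default
#'   `[anesthesia_start - 100, anesthesia_start)`.
#' @param baseline_len_s Length of the default baseline window (s, 100).
#' @return A `dff_trace` list: `dff`, `fs_hz`, `f0_au`, `baseline_window`,
#'   plus the trace's annotations and ids.
#' @export
compute_dff <- function(trace, baseline_window = NULL, baseline_len_s = 100) {
  if (!inherits(trace, "photometry_trace")) {
    stop_validation("trace must be a photometry_trace")
  }
  if (is.null(baseline_window)) {
    if (is.null(trace$anesthesia_start_s)) {
      stop_parameter("no anesthesia annotations; supply baseline_window")
    }
    baseline_window <- c(max(0, trace$anesthesia_start_s - baseline_len_s),
                         trace$anesthesia_start_s)
  }
  check_window(baseline_window, "baseline_window")
  dur <- length(trace$f_au) / trace$fs_hz
  if (baseline_window[1] < 0 || baseline_window[2] > dur + 1e-9) {
    stop_parameter("baseline_window [%g, %g) outside the trace (0-%g s)",
                   baseline_window[1], baseline_window[2], dur)
  }
  idx <- window_indices(baseline_window, trace$fs_hz, length(trace$f_au))
  f0 <- mean(trace$f_au[idx])
  if (!is.finite(f0) || f0 <= 0) {
    stop_validation("baseline mean fluorescence must be > 0 (got %g)", f0)
  }
  structure(list(
    dff = (trace$f_au - f0) / f0, fs_hz = trace$fs_hz, f0_au = f0,
    baseline_window = baseline_window,
    anesthesia_start_s = trace$anesthesia_start_s,
    anesthesia_end_s = trace$anesthesia_end_s,
    subject_id = trace$subject_id, group_label = trace$group_label
  ), class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %s: %d samples @ %g Hz, F0 = %.3f (baseline [%g, %g) s)\n",
              if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
              length(x$dff), x$fs_hz, x$f0_au,
              x$baseline_window[1], x$baseline_window[2]))
  invisible(x)
}

# Sample indices whose start times fall in the half-open window.
window_indices <- function(window, fs, n) {
  i0 <- floor(window[1] * fs + 1e-9) + 1L
  i1 <- ceiling(window[2] * fs - 1e-9)
  i0 <- max(1L, i0); i1 <- min(n, i1)
  if (i1 < i0) stop_parameter("window [%g, %g) contains no samples",
                              window[1], window[2])
  i0:i1
}

#' Pre- versus during-anesthesia dF/F change
#'
#' Means of dF/F over a pre-anesthesia window and the anesthesia window, and
#' their difference (during minus pre).
#'
#' @param dff A `dff_trace` from [compute_dff()].
#' @param pre_window `c(start_s, end_s)`; default the baseline window.
#' @param during_window `c(start_s, end_s)`; default the anesthesia window.
#' @return An `epoch_change` list: `pre_mean`, `during_mean`, `change`.
#' @export
epoch_change <- function(dff, pre_window = NULL, during_window = NULL) {
  if (!inherits(dff, "dff_trace")) stop_validation("dff must be a dff_trace")
  if (is.null(pre_window)) pre_window <- dff$baseline_window
  if (is.null(during_window)) {
    if (is.null(dff$anesthesia_start_s)) {
      stop_parameter("no anesthesia annotations; supply during_window")
    }
    during_window <- c(dff$anesthesia_start_s, dff$anesthesia_end_s)
  }
  check_window(pre_window, "pre_window")
  check_window(during_window, "during_window")
  if (pre_window[2] > during_window[1] && during_window[2] > pre_window[1]) {
    stop_parameter("pre and during windows must be disjoint")
  }
  n <- length(dff$dff)
  pre_mean <- mean(dff$dff[window_indices(pre_window, dff$fs_hz, n)])
  during_mean <- mean(dff$dff[window_indices(during_window, dff$fs_hz, n)])
  structure(list(pre_window = pre_window, during_window = during_window,
                 pre_mean = pre_mean, during_mean = during_mean,
                 change = during_mean - pre_mean,
                 subject_id = dff$subject_id, group_label = dff$group_label),
            class = "epoch_change")
}

#' @export
print.epoch_change <- function(x, ...) {
  cat(sprintf("<epoch_change> pre %.4f, during %.4f, change %+.4f\n",
              x$pre_mean, x$during_mean, x$change))
  invisible(x)
}

#' Group-mean dF/F trace with per-point SEM
#'
#' Aligns traces at their anesthesia onsets (or at supplied times), truncates
#' to the common support, and returns the per-point mean and standard error
#' of the mean (SD / sqrt(n)).
#'
#' @param dffs List of `dff_trace` objects sharing one sampling rate.
#' @param align_at_s Optional numeric vector of alignment times (s), one per
#'   trace; defaults to each trace's anesthesia onset.
#' @return A data.frame `time_s` (relative to alignment, 0 at onset),
#'   `mean`, `sem`, `n`.
#' @export
group_mean_trace <- function(dffs, align_at_s = NULL) {
  if (!is.list(dffs) || length(dffs) < 2L) {
    stop_validation("need at least 2 traces to form a SEM")
  }
  if (!all(vapply(dffs, inherits, logical(1), "dff_trace"))) {
    stop_validation("all elements must be dff_trace objects")
  }
  fs <- dffs[[1]]$fs_hz
  if (any(abs(vapply(dffs, function(d) d$fs_hz, numeric(1)) - fs) > 1e-9)) {
    stop_validation("all traces must share one sampling rate")
  }
  if (is.null(align_at_s)) {
    align_at_s <- vapply(dffs, function(d) {
      if (is.null(d$anesthesia_start_s)) {
        stop_parameter("trace lacks anesthesia annotations; supply align_at_s")
      }
      d$anesthesia_start_s
    }, numeric(1))
  }
  align_i <- round(align_at_s * fs)        # samples before alignment point
  n_i <- vapply(dffs, function(d) length(d$dff), numeric(1))
  if (any(align_i < 0) || any(align_i > n_i)) {
    stop_parameter("alignment time outside a trace")
  }
  pre_n <- min(align_i)
  post_n <- min(n_i - align_i)
  mat <- vapply(seq_along(dffs), function(k) {
    i0 <- align_i[k] - pre_n + 1L
    dffs[[k]]$dff[i0:(align_i[k] + post_n)]
  }, numeric(pre_n + post_n))
  m <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  data.frame(time_s = (seq_len(pre_n + post_n) - 1L - pre_n) / fs,
             mean = m, sem = sdv / sqrt(length(dffs)), n = length(dffs))
}
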