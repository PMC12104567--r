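# Containers and file I/O for EEG and photometry traces, plus the recording
# band filter.

#' Construct an EEG recording
#'
#' An `eeg_recording` holds a single-channel amplitude series in microvolts
#' together with its sampling rate and optional anesthesia-window annotations.
#' Time is in seconds from record start (0-based); annotation windows are
#' half-open `[start, end)`.
#'
#' @param samples Numeric vector of amplitudes (uV); all values must be finite.
#' @param fs_hz Sampling rate in Hz (> 0).
#' @param start_time_s Time of the first sample, seconds (default 0).
#' @param anesthesia_start_s,anesthesia_end_s Optional anesthesia window in
#'   seconds from record start; must satisfy
#'   `0 <= start < end <= n_samples / fs_hz`.
#' @param subject_id Subject identifier string.
#' @param group_label Optional group label.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs_hz, start_time_s = 0,
                          anesthesia_start_s = NULL, anesthesia_end_s = NULL,
                          subject_id = "", group_label = NULL) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop_validation("samples must be a non-empty numeric vector")
  }
  if (any(!is.finite(samples))) {
    stop_validation("samples contains non-finite values")
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0) {
    stop_validation("fs_hz must be a single positive number")
  }
  dur <- length(samples) / fs_hz
  has_ann <- !is.null(anesthesia_start_s) && !is.null(anesthesia_end_s)
  if (has_ann) {
    if (anesthesia_start_s < 0 || anesthesia_start_s >= anesthesia_end_s ||
        anesthesia_end_s > dur + 1e-9) {
      stop_validation(
        "anesthesia window [%g, %g) must satisfy 0 <= start < end <= %g",
        anesthesia_start_s, anesthesia_end_s, dur)
    }
  }
  structure(list(
    samples = as.numeric(samples),
    fs_hz = as.numeric(fs_hz),
    start_time_s = as.numeric(start_time_s),
    anesthesia_start_s = if (has_ann) as.numeric(anesthesia_start_s) else NULL,
    anesthesia_end_s = if (has_ann) as.numeric(anesthesia_end_s) else NULL,
    subject_id = as.character(subject_id),
    group_label = if (is.null(group_label)) NULL else as.character(group_label)
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s%s: %d samples @ %g Hz (%.1f s)\n",
              if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
              if (!is.null(x$group_label)) paste0(" [", x$group_label, "]") else "",
              length(x$samples), x$fs_hz, length(x$samples) / x$fs_hz))
  if (!is.null(x$anesthesia_start_s)) {
    cat(sprintf("  anesthesia window: [%g, %g) s\n",
                x$anesthesia_start_s, x$anesthesia_end_s))
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording` or `photometry_trace`.
#' @return Duration in seconds.
#' @export
rec_duration_s <- function(rec) {
  n <- if (inherits(rec, "photometry_trace")) length(rec$f_au) else length(rec$samples)
  n / rec$fs_hz
}

# The anesthesia window of a recording, or an error if absent.
anesthesia_window <- function(rec) {
  if (is.null(rec$anesthesia_start_s)) {
    stop_parameter("recording has no anesthesia annotations; supply a window explicitly")
  }
  c(rec$anesthesia_start_s, rec$anesthesia_end_s)
}

#' Construct a fiber-photometry trace
#'
#' @param f_au Numeric fluorescence series (arbitrary units), finite.
#' @param fs_hz Sampling rate in Hz (> 0).
#' @param anesthesia_start_s,anesthesia_end_s Optional anesthesia window (s).
#' @param subject_id Subject identifier.
#' @param group_label Optional group label.
#' @return An object of class `photometry_trace`.
#' @export
photometry_trace <- function(f_au, fs_hz, anesthesia_start_s = NULL,
                             anesthesia_end_s = NULL, subject_id = "",
                             group_label = NULL) {
  if (!is.numeric(f_au) || length(f_au) == 0L || any(!is.finite(f_au))) {
    stop_validation("f_au must be a non-empty finite numeric vector")
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    stop_validation("fs_hz must be a single positive number")
  }
  dur <- length(f_au) / fs_hz
  has_ann <- !is.null(anesthesia_start_s) && !is.null(anesthesia_end_s)
  if (has_ann && (anesthesia_start_s < 0 || anesthesia_start_s >= anesthesia_end_s ||
                  anesthesia_end_s > dur + 1e-9)) {
    stop_validation("anesthesia window [%g, %g) out of range for a %.1f s trace",
                    anesthesia_start_s, anesthesia_end_s, dur)
  }
  structure(list(
    f_au = as.numeric(f_au), fs_hz = as.numeric(fs_hz),
    anesthesia_start_s = if (has_ann) as.numeric(anesthesia_start_s) else NULL,
    anesthesia_end_s = if (has_ann) as.numeric(anesthesia_end_s) else NULL,
    subject_id = as.character(subject_id),
    group_label = if (is.null(group_label)) NULL else as.character(group_label)
  ), class = "photometry_trace")
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat(sprintf("<photometry_trace> %s: %d samples @ %g Hz (%.1f s)\n",
              if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
              length(x$f_au), x$fs_hz, length(x$f_au) / x$fs_hz))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Sidecar annotations (JSON): {"anesthesia_start_s": ..., "anesthesia_end_s": ...}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".annotations.json")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  ann <- jsonlite::read_json(sp, simplifyVector = TRUE)
  list(start = ann$anesthesia_start_s, end = ann$anesthesia_end_s,
       subject_id = ann$subject_id, group_label = ann$group_label)
}

write_sidecar <- function(rec, path) {
  ann <- list(subject_id = rec$subject_id)
  if (!is.null(rec$anesthesia_start_s)) {
    ann$anesthesia_start_s <- rec$anesthesia_start_s
    ann$anesthesia_end_s <- rec$anesthesia_end_s
  }
  if (!is.null(rec$group_label)) ann$group_label <- rec$group_label
  jsonlite::write_json(ann, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

# ---------------------------------------------------------------------------
# TSV dialect: tab separator, dot decimal, header row, UTF-8, one channel.

read_trace_tsv <- function(path, value_col) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "numeric", check.names = FALSE)
  if (!all(c("time_s", value_col) %in% names(df))) {
    stop_parse("TSV %s must have columns 'time_s' and '%s'", path, value_col)
  }
  t <- df$time_s
  if (length(t) < 2L) stop_parse("TSV %s has fewer than 2 samples", path)
  dt <- diff(t)
  med <- stats::median(dt)
  if (med <= 0 || max(abs(dt - med)) > 1e-6 * med) {
    stop_parse("TSV %s has a non-uniform timebase (tolerance 1 ppm)", path)
  }
  list(values = df[[value_col]], fs_hz = 1 / med)
}

write_trace_tsv <- function(values, fs_hz, path, value_col) {
  t <- (seq_along(values) - 1L) / fs_hz
  df <- data.frame(time_s = t, v = values)
  names(df)[2] <- value_col
  ok <- tryCatch({
    utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write TSV to %s", path)
  invisible(path)
}

#' Read an EEG recording from EDF or TSV
#'
#' TSV input must have columns `time_s` and `amplitude_uv` with a uniform
#' timebase (within 1 ppm); the sampling rate is inferred from the median time
#' step. EDF input is read from the first signal of a standard (16-bit) EDF
#' file. Anesthesia annotations are taken from a sidecar
#' `<name>.annotations.json` file when present.
#'
#' @param path Input file path.
#' @param format One of `"auto"` (by extension), `"tsv"`, `"edf"`.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, format = c("auto", "tsv", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io("file not found: %s", path)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "edf") "edf" else "tsv"
  }
  if (format == "edf") {
    sig <- read_edf_signal(path)
    samples <- sig$values; fs <- sig$fs_hz
  } else {
    tr <- read_trace_tsv(path, "amplitude_uv")
    samples <- tr$values; fs <- tr$fs_hz
  }
  ann <- read_sidecar(path)
  eeg_recording(samples, fs,
                anesthesia_start_s = ann$start, anesthesia_end_s = ann$end,
                subject_id = if (!is.null(ann$subject_id)) ann$subject_id else
                  tools::file_path_sans_ext(basename(path)),
                group_label = ann$group_label)
}

#' Write an EEG recording to EDF or TSV
#'
#' TSV output is written at full double precision and round-trips exactly;
#' EDF output is 16-bit with a physical range covering the observed
#' amplitudes, so round-trip error is bounded by the quantization step.
#' Anesthesia annotations, subject id and group label are written to a
#' sidecar `<name>.annotations.json`.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @param format One of `"auto"`, `"tsv"`, `"edf"`.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path, format = c("auto", "tsv", "edf")) {
  if (!inherits(rec, "eeg_recording")) {
    stop_validation("rec must be an eeg_recording")
  }
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "edf") "edf" else "tsv"
  }
  if (format == "edf") {
    write_edf_signal(rec$samples, rec$fs_hz, path, label = "EEG",
                     phys_dim = "uV")
  } else {
    write_trace_tsv(rec$samples, rec$fs_hz, path, "amplitude_uv")
  }
  write_sidecar(rec, path)
  invisible(path)
}

#' Read a photometry trace from TSV
#'
#' Expects columns `time_s` and `F_au`; annotations from a sidecar JSON.
#'
#' @param path Input TSV path.
#' @return A [photometry_trace()].
#' @export
read_photometry <- function(path) {
  tr <- read_trace_tsv(path, "F_au")
  ann <- read_sidecar(path)
  photometry_trace(tr$values, tr$fs_hz,
                   anesthesia_start_s = ann$start, anesthesia_end_s = ann$end,
                   subject_id = if (!is.null(ann$subject_id)) ann$subject_id else
                     tools::file_path_sans_ext(basename(path)),
                   group_label = ann$group_label)
}

#' Write a photometry trace to TSV
#'
#' @param trace A [photometry_trace()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_photometry <- function(trace, path) {
  if (!inherits(trace, "photometry_trace")) {
    stop_validation("trace must be a photometry_trace")
  }
  write_trace_tsv(trace$f_au, trace$fs_hz, path, "F_au")
  write_sidecar(trace, path)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Apply the recording-band filter
#'
#' Band-pass filters a recording with a 4th-order Butterworth filter, by
#' default 0.5-70 Hz applied forward-backward (zero phase) so that suppression
#' event onsets and offsets are not shifted in time. Output length equals
#' input length and all metadata are preserved.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs_hz / 2`.
#' @param order Butterworth order (default 4).
#' @param zero_phase If `TRUE` (default) filter forward-backward
#'   (`signal::filtfilt`); if `FALSE`, a single causal pass.
#' @return A filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, low_hz = 0.5, high_hz = 70, order = 4L,
                            zero_phase = TRUE) {
  if (!inherits(rec, "eeg_recording")) stop_validation("rec must be an eeg_recording")
  nyq <- rec$fs_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop_parameter("band edges must satisfy 0 < low_hz < high_hz < fs/2 = %g", nyq)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  y <- if (zero_phase) signal::filtfilt(bf, rec$samples)
       else as.numeric(signal::filter(bf, rec$samples))
  out <- rec
  out$samples <- as.numeric(y)[seq_along(rec$samples)]
  out
}
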