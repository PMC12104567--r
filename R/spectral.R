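# Welch power spectral density, spectrograms and relative band power in the
# four reported EEG bands.

#' Canonical EEG band edges
#'
#' delta 0.5-4 Hz, theta 4-8 Hz, alpha 8-15 Hz, beta 15-25 Hz; all bands are
#' half-open `[lo, hi)` so shared edges are not double counted.
#'
#' @return Named list of `c(lo, hi)` band edges in Hz.
#' @export
default_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 15), beta = c(15, 25))
}

hamming_win <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

#' Welch power spectral density estimate
#'
#' Averaged Hamming-tapered periodograms over overlapping segments, with
#' one-sided density scaling (power/Hz): integrating the PSD over frequency
#' recovers the signal variance (Parseval). Segment means are removed before
#' tapering.
#'
#' @param x Numeric signal.
#' @param fs_hz Sampling rate (Hz).
#' @param seg_s Segment length in seconds (default 2).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @return A list with `freq_hz` and `psd` (uV^2/Hz for uV input).
#' @export
welch_psd <- function(x, fs_hz, seg_s = 2, overlap = 0.5) {
  nseg <- round(seg_s * fs_hz)
  if (nseg < 8L) stop_parameter("segment must contain at least 8 samples")
  if (overlap < 0 || overlap >= 1) stop_parameter("overlap must be in [0, 1)")
  if (nseg > length(x)) stop_parameter("segment longer than the signal")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- hamming_win(nseg)
  u <- sum(w^2)                       # window power normalization
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs_hz * u)
  # one-sided: double everything except DC and (for even nseg) Nyquist
  idx <- 2L:(nfreq - if (nseg %% 2L == 0L) 1L else 0L)
  psd[idx] <- 2 * psd[idx]
  list(freq_hz = (seq_len(nfreq) - 1L) * fs_hz / nseg, psd = psd)
}

#' Short-time spectrogram of a recording
#'
#' One Hamming-tapered periodogram per segment with density scaling, on
#' overlapping segments (default 2 s, 75% overlap).
#'
#' @param rec An [eeg_recording()].
#' @param seg_s Segment length (s).
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return An `eeg_spectrogram` list: `times_s` (segment centers),
#'   `freqs_hz`, `power` (matrix, freq x time, uV^2/Hz).
#' @export
eeg_spectrogram <- function(rec, seg_s = 2, overlap = 0.75) {
  if (!inherits(rec, "eeg_recording")) stop_validation("rec must be an eeg_recording")
  fs <- rec$fs_hz
  nseg <- round(seg_s * fs)
  if (nseg < 8L) stop_parameter("segment must contain at least 8 samples")
  if (nseg > length(rec$samples)) stop_parameter("segment longer than the record")
  if (overlap < 0 || overlap >= 1) stop_parameter("overlap must be in [0, 1)")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(rec$samples) - nseg + 1L, by = step)
  w <- hamming_win(nseg)
  u <- sum(w^2)
  nfreq <- nseg %/% 2L + 1L
  power <- matrix(0, nrow = nfreq, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- rec$samples[starts[j]:(starts[j] + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2 / (fs * u)
    idx <- 2L:(nfreq - if (nseg %% 2L == 0L) 1L else 0L)
    sp[idx] <- 2 * sp[idx]
    power[, j] <- sp
  }
  structure(list(times_s = (starts - 1L + nseg / 2) / fs,
                 freqs_hz = (seq_len(nfreq) - 1L) * fs / nseg,
                 power = power),
            class = "eeg_spectrogram")
}

#' @export
print.eeg_spectrogram <- function(x, ...) {
  cat(sprintf("<eeg_spectrogram> %d freqs x %d segments (%.2g-%.4g Hz)\n",
              length(x$freqs_hz), length(x$times_s),
              min(x$freqs_hz), max(x$freqs_hz)))
  invisible(x)
}

#' Relative band power over an analysis window
#'
#' Welch PSD over the window (2-s Hamming segments, 50% overlap), band power
#' as the rectangle-rule sum of the PSD over frequency bins in each half-open
#' band, and relative power as band power divided by the total over the union
#' of the reported bands (default 0.5-25 Hz), so the four fractions form a
#' composition summing to 1.
#'
#' @param rec An [eeg_recording()].
#' @param window Analysis window `c(start_s, end_s)`; defaults to the
#'   anesthesia annotations. Must be at least 8 s long.
#' @param bands Named list of half-open band edges (default [default_bands()]).
#' @param total_range Denominator range in Hz (default `c(0.5, 25)`, the
#'   union of the four bands).
#' @param seg_s,overlap Welch parameters (defaults 2 s, 0.5).
#' @return A `band_power_table` data.frame: `band`, `lo_hz`, `hi_hz`,
#'   `power`, `rel_power`; attribute `window`.
#' @export
relative_band_power <- function(rec, window = NULL, bands = default_bands(),
                                total_range = c(0.5, 25), seg_s = 2,
                                overlap = 0.5) {
  if (!inherits(rec, "eeg_recording")) stop_validation("rec must be an eeg_recording")
  if (is.null(window)) window <- anesthesia_window(rec)
  check_window(window)
  fs <- rec$fs_hz
  dur <- length(rec$samples) / fs
  if (window[1] < 0 || window[2] > dur + 1e-9) {
    stop_parameter("window [%g, %g) outside the record (0-%g s)",
                   window[1], window[2], dur)
  }
  if (window[2] - window[1] < 8) {
    stop_parameter("analysis window must be at least 8 s long")
  }
  i0 <- floor(window[1] * fs) + 1L
  i1 <- min(length(rec$samples), ceiling(window[2] * fs))
  p <- welch_psd(rec$samples[i0:i1], fs, seg_s = seg_s, overlap = overlap)
  df_hz <- p$freq_hz[2] - p$freq_hz[1]
  band_power <- vapply(bands, function(b) {
    sel <- p$freq_hz >= b[1] & p$freq_hz < b[2]
    sum(p$psd[sel]) * df_hz
  }, numeric(1))
  tot_sel <- p$freq_hz >= total_range[1] & p$freq_hz < total_range[2]
  total <- sum(p$psd[tot_sel]) * df_hz
  if (total <= 0) stop_validation("total power over %g-%g Hz is zero",
                                  total_range[1], total_range[2])
  out <- data.frame(band = names(bands),
                    lo_hz = vapply(bands, `[`, numeric(1), 1),
                    hi_hz = vapply(bands, `[`, numeric(1), 2),
                    power = unname(band_power),
                    rel_power = unname(band_power) / total,
                    row.names = NULL)
  class(out) <- c("band_power_table", "data.frame")
  attr(out, "window") <- window
  attr(out, "total_range") <- total_range
  out
}
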