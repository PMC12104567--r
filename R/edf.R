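# Minimal single-channel European Data Format (EDF, 16-bit) reader/writer.
# Standard EDF only: ASCII fixed-width header, little-endian int16 samples,
# linear digital-to-physical scaling. One data record holding the whole
# signal keeps arbitrary (non-integer-second) durations exact.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop_io("EDF header field too wide: '%s' (max %d)", s, width)
  formatC(s, width = -width, flag = " ")
}

# Format a number into <= `width` ASCII chars, trimming precision as needed.
edf_num <- function(v, width = 8L) {
  for (d in seq(7, 1)) {
    s <- formatC(v, digits = d, format = "g", width = -1)
    if (nchar(s) <= width) return(edf_field(s, width))
  }
  stop_io("cannot format %g into %d EDF header characters", v, width)
}

write_edf_signal <- function(values, fs_hz, path, label = "EEG",
                             phys_dim = "uV") {
  if (length(values) == 0L) stop_validation("cannot write an empty EDF signal")
  n <- length(values)
  m <- max(max(abs(values)), 1)        # symmetric physical range
  phys_min <- -m; phys_max <- m
  dig_min <- -32767L; dig_max <- 32767L
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- as.integer(round((values - phys_min) / scale)) + dig_min

  hdr <- paste0(
    edf_field("0", 8),                         # version
    edf_field("X X X X", 80),                  # patient id (anonymous)
    edf_field("Startdate X X X X", 80),        # recording id
    edf_field("01.01.00", 8),                  # start date (fixed)
    edf_field("00.00.00", 8),                  # start time (fixed)
    edf_field(256L * 2L, 8),                   # header bytes (1 signal)
    edf_field("", 44),                         # reserved
    edf_field(1L, 8),                          # number of data records
    edf_num(n / fs_hz, 8),                     # record duration (s)
    edf_field(1L, 4)                           # number of signals
  )
  sig <- paste0(
    edf_field(label, 16),
    edf_field("", 80),                         # transducer
    edf_field(phys_dim, 8),
    edf_num(phys_min, 8),
    edf_num(phys_max, 8),
    edf_field(dig_min, 8),
    edf_field(dig_max, 8),
    edf_field("", 80),                         # prefiltering
    edf_field(n, 8),                           # samples per record
    edf_field("", 32)                          # reserved
  )
  con <- tryCatch(file(path, "wb"), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(con)) stop_io("cannot open %s for writing", path)
  on.exit(close(con))
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

read_edf_signal <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_hdr <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(raw_hdr, type = "bytes") < 256L) stop_parse("truncated EDF header in %s", path)
  fld <- function(hdr, from, len) substr(hdr, from, from + len - 1L)
  num <- function(s) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (is.na(v)) stop_parse("malformed EDF header numeric field '%s' in %s", s, path)
    v
  }
  n_rec <- num(fld(raw_hdr, 237, 8))
  rec_dur <- num(fld(raw_hdr, 245, 8))
  ns <- as.integer(num(fld(raw_hdr, 253, 4)))
  if (ns < 1L) stop_parse("EDF file %s declares no signals", path)
  sig_hdr <- readChar(con, 256L * ns, useBytes = TRUE)
  # signal header layout: 16 label, 80 transducer, 8 dim, 8x4 ranges, 80, 8, 32
  labels <- vapply(seq_len(ns), function(i)
    substr(sig_hdr, (i - 1L) * 16L + 1L, i * 16L), character(1))
  off <- 16L * ns + 80L * ns + 8L * ns                   # bytes before phys_min block
  get_num_block <- function(block_start) {
    vapply(seq_len(ns), function(i) {
      num(substr(sig_hdr, block_start + (i - 1L) * 8L + 1L,
                 block_start + i * 8L))
    }, numeric(1))
  }
  phys_min <- get_num_block(off)
  phys_max <- get_num_block(off + 8L * ns)
  dig_min <- get_num_block(off + 16L * ns)
  dig_max <- get_num_block(off + 24L * ns)
  spr <- get_num_block(off + 32L * ns + 80L * ns)        # samples per record
  if (any(dig_max <= dig_min) || any(phys_max <= phys_min)) {
    stop_parse("EDF file %s has a degenerate scaling range", path)
  }
  target <- which(grepl("EEG", labels, ignore.case = TRUE))
  target <- if (length(target)) target[1] else 1L
  values <- numeric(0)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      block <- readBin(con, "integer", n = spr[s], size = 2L, endian = "little")
      if (length(block) < spr[s]) stop_parse("truncated EDF data in %s", path)
      if (s == target) values <- c(values, block)
    }
  }
  scale <- (phys_max[target] - phys_min[target]) /
    (dig_max[target] - dig_min[target])
  phys <- (values - dig_min[target]) * scale + phys_min[target]
  fs <- spr[target] / rec_dur
  list(values = phys, fs_hz = fs, label = trimws(labels[target]))
}
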