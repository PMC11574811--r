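# Minimal European Data Format (EDF) support: ASCII header plus 16-bit
# little-endian data records. Covers the subset this package needs --
# equal sampling rate across signals, 1-second data records -- which is
# the common case for continuous resting-state EEG.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(s, width)
}

write_edf <- function(rec, path) {
  fs <- rec$fs
  ns <- n_channels(rec)
  n <- n_samples(rec)
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires an integer sampling rate")
  if (n %% fs != 0) stop("EDF export requires a whole number of seconds")
  n_rec <- n %/% fs

  phys_min <- apply(rec$data, 1L, min)
  phys_max <- apply(rec$data, 1L, max)
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)

  wr(edf_pad("0", 8))                       # version
  wr(edf_pad(rec$id, 80))                   # patient id field reused as id
  wr(edf_pad(rec$id, 80))                   # recording id
  wr(edf_pad("01.01.20", 8))                # start date (synthetic)
  wr(edf_pad("00.00.00", 8))                # start time
  wr(edf_pad(256 * (ns + 1), 8))            # header bytes
  wr(edf_pad("", 44))                       # reserved
  wr(edf_pad(n_rec, 8))                     # number of data records
  wr(edf_pad("1", 8))                       # record duration, seconds
  wr(edf_pad(ns, 4))                        # number of signals

  for (lab in rec$channel_labels) wr(edf_pad(lab, 16))
  for (i in seq_len(ns)) wr(edf_pad("", 80))        # transducer
  for (i in seq_len(ns)) wr(edf_pad("uV", 8))       # physical dimension
  for (i in seq_len(ns)) wr(edf_num(phys_min[i], 8))
  for (i in seq_len(ns)) wr(edf_num(phys_max[i], 8))
  for (i in seq_len(ns)) wr(edf_pad(dig_min, 8))
  for (i in seq_len(ns)) wr(edf_pad(dig_max, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))        # prefiltering
  for (i in seq_len(ns)) wr(edf_pad(fs, 8))         # samples per record
  for (i in seq_len(ns)) wr(edf_pad("", 32))        # reserved

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((rec$data[i, idx] - phys_min[i]) * scale[i]) + dig_min
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))

  rd(8); id <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header")

  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  if (anyDuplicated(labels)) stop("duplicated channel labels in EDF header")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) {
    stop("EDF files with per-signal sampling rates are not supported")
  }
  fs <- spr[1L] / rec_dur

  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      data[i, idx] <- (dig - dig_min[i]) * gain[i] + phys_min[i]
    }
  }
  eeg_recording(data, fs = fs, channel_labels = labels,
                id = if (nzchar(id)) id else basename(path))
}
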