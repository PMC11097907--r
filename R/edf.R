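# Minimal European Data Format (EDF) input/output.
#
# Supports the plain EDF profile this package needs: equal sampling rate
# across signals, 16-bit samples, one-second data records. Written because
# no installed package reads EDF; the format is an ASCII header followed by
# little-endian int16 data records.

pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' One-second data records; samples are linearly quantized to int16 over
#' each channel's observed range. A trailing partial second is dropped.
#'
#' @param rec An `eeg_recording` with an integer sampling rate.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"),
            abs(rec$rate - round(rec$rate)) < 1e-9)
  rate <- round(rec$rate)
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / rate)
  stopifnot(n_rec >= 1)
  x <- rec$data[, seq_len(n_rec * rate), drop = FALSE]
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  pmax_[pmax_ == pmin_] <- pmin_[pmax_ == pmin_] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("", 80), pad("", 80),
                pad("01.01.00", 8), pad("00.00.00", 8),
                pad(256 + ns * 256, 8), pad("", 44),
                pad(n_rec, 8), pad(1, 8), pad(ns, 4))
  field <- function(vals, width)
    paste(vapply(vals, pad, character(1), width = width), collapse = "")
  hdr <- paste0(hdr,
    field(rec$channel_labels, 16),
    field(rep("", ns), 80),
    field(rep("uV", ns), 8),
    field(formatC(pmin_, digits = 5, format = "g"), 8),
    field(formatC(pmax_, digits = 5, format = "g"), 8),
    field(rep(dmin, ns), 8),
    field(rep(dmax, ns), 8),
    field(rep("", ns), 80),
    field(rep(rate, ns), 8),
    field(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)
  # reread the printed physical range so the stored scaling matches exactly
  pmin_w <- as.numeric(formatC(pmin_, digits = 5, format = "g"))
  pmax_w <- as.numeric(formatC(pmax_, digits = 5, format = "g"))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- x[i, ((r - 1) * rate + 1):(r * rate)]
      dig <- round((seg - pmin_w[i]) / (pmax_w[i] - pmin_w[i]) *
                     (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads plain EDF with a common sampling rate across signals.
#'
#' @param path Input path.
#' @param condition Condition tag to attach.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, condition = "unknown") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) {
    trimws(readChar(con, nchars, useBytes = TRUE))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header size
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("only a common sampling rate across signals is supported")
  out <- matrix(NA_real_, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmin[i]) / (dmax[i] - dmin[i]) *
        (pmax_[i] - pmin_[i]) + pmin_[i]
      out[i, ((r - 1) * spr[1] + 1):(r * spr[1])] <- phys
    }
  }
  eeg_recording(out, spr[1] / rec_dur, labels, condition)
}
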