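# Minimal EDF (European Data Format) reader and writer.
#
# Supports the continuous-recording subset the pipeline needs: standard
# 256-byte header, per-signal headers, 16-bit little-endian samples, equal
# sampling rate across signals, 1-second data records. No annotations, no
# EDF+ discontinuities. Implemented here because no EDF package is available
# as a dependency.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' One-second data records; trailing samples that do not fill a whole record
#' are dropped (EDF stores an integer number of records). Each channel gets a
#' symmetric physical range covering its data, so the 16-bit quantization
#' step is `range/65535`.
#'
#' @param rec an [eeg_recording()]; `fs` must be a whole number.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1) stop("recording shorter than one 1-second data record")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmaxabs <- pmax(apply(abs(data), 1, max), 1e-3)
  phys_min <- -pmaxabs
  phys_max <- pmaxabs
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    edf_pad("0", 8),
    edf_pad(paste0("subject ", rec$subject_id), 80),
    edf_pad(paste0("condition ", rec$condition), 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4)
  ), con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, edf_pad, character(1), width = width),
                    collapse = ""), con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("", ns), 80)                      # transducer
  field(rep("uV", ns), 8)                     # physical dimension
  field(sprintf("%.6g", phys_min), 8)
  field(sprintf("%.6g", phys_max), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                      # prefiltering
  field(rep(fs, ns), 8)                       # samples per record
  field(rep("", ns), 32)
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, idx] - phys_min[ch]) * gain[ch] + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads the continuous-EDF subset written by [write_edf()] (and plain EDF
#' files with equal per-signal sampling rates and no annotation channel).
#'
#' @param path EDF file path.
#' @return List: `data` (channels x samples matrix, physical units),
#'   `fs`, `channel_labels`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256) stop("not an EDF file: truncated header")
  gethdr <- function(from, len) trimws(substr(hdr, from, from + len - 1))
  n_rec <- as.integer(gethdr(237, 8))
  rec_dur <- as.numeric(gethdr(245, 8))
  ns <- as.integer(gethdr(253, 4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) stop("unparseable EDF header")
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  grab <- function(offset, width) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, offset + (i - 1) * width + 1,
                    offset + i * width)), character(1))
  }
  labels <- grab(0, 16)
  phys_min <- as.numeric(grab(ns * (16 + 80 + 8), 8))
  phys_max <- as.numeric(grab(ns * (16 + 80 + 8 + 8), 8))
  dig_min <- as.numeric(grab(ns * (16 + 80 + 8 + 8 + 8), 8))
  dig_max <- as.numeric(grab(ns * (16 + 80 + 8 + 8 + 8 + 8), 8))
  spr <- as.integer(grab(ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), 8))
  if (length(unique(spr)) != 1)
    stop("unsupported EDF: signals have different sampling rates")
  fs <- spr[1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little", signed = TRUE)
    if (length(raw) < ns * spr[1]) stop("truncated EDF data")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- t(block) * gain + (phys_min - dig_min * gain)
  }
  list(data = data, fs = fs, channel_labels = labels)
}
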