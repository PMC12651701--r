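# Minimal EDF (European Data Format) writer/reader: 16-bit integer samples,
# one data record per second, ASCII fixed-width header.  Covers plain EDF
# with identical per-signal rates -- sufficient for 10-20 montage exports.
# Quantization to the 16-bit digital range makes the round trip lossy at
# roughly (phys_max - phys_min)/65535 resolution.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write an EEG recording to an EDF file
#'
#' Signals are scaled per channel to the 16-bit digital range; the trailing
#' partial second (EDF stores whole one-second records) is dropped.
#'
#' @param rec An [eeg_recording()]; `rate` must be a whole number.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate != round(rec$rate))
    stop("EDF export requires an integer sampling rate", call. = FALSE)
  spr <- as.integer(rec$rate)           # samples per 1-s record
  n_rec <- ncol(rec$data) %/% spr
  if (n_rec < 1L) stop("recording shorter than one EDF record", call. = FALSE)
  ns <- nrow(rec$data)
  x <- rec$data[, seq_len(n_rec * spr), drop = FALSE]

  # integer physical limits: exact to parse back from the 8-char fields
  pmin_ <- floor(apply(x, 1, min)); pmax_ <- ceiling(apply(x, 1, max))
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  gain <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- round((x - pmin_) * gain + dmin)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr(rec$subject_id, 80)
  wr(paste("Startdate 01-JAN-2000 condition", rec$condition), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1L), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (lab in rec$channel_labels) wr(paste("EEG", lab), 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in pmin_) wr(sprintf("%d", as.integer(v)), 8)
  for (v in pmax_) wr(sprintf("%d", as.integer(v)), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, cols])), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEG recording
#'
#' Supports the subset written by [write_edf()]: identical sampling rate on
#' every signal, whole-second records.  Channel labels are taken from the
#' signal labels with any `"EEG "` prefix stripped.
#'
#' @param path EDF file path.
#' @param subject_id,condition Optional overrides; defaults come from the
#'   header's patient field and recording field.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, subject_id = NULL, condition = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                   # version
  pat <- rd(80); rec_field <- rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8)); dur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  labs <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal rates are not supported", call. = FALSE)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    blk <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little")
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, cols] <- matrix(blk, nrow = spr[1])[, seq_len(ns)] |> t()
  }
  data <- (data - dmin) * gain + pmin_
  labs <- sub("^EEG ", "", labs)
  cond <- condition %||% sub(".*condition ", "", rec_field)
  eeg_recording(data, rate = spr[1] / dur, channel_labels = labs,
                subject_id = subject_id %||% pat, condition = cond)
}
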