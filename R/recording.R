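#' Construct an EEG recording object
#'
#' A thin container for a channels-by-samples block of EEG amplitude
#' (microvolts) with its sampling rate, ordered channel labels, subject id
#' and condition tag.  All pipeline stages consume and return this class.
#'
#' @param data Numeric matrix, channels x samples (rows ordered as
#'   `channel_labels`).
#' @param rate Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of 16 unique montage labels
#'   (see [montage_channels()]).
#' @param subject_id Subject identifier (scalar, coerced to character).
#' @param condition Condition tag, typically `"pre"` or `"post"`.
#' @return An object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(data, rate, channel_labels = montage_channels(),
                          subject_id = "s1", condition = "pre") {
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric channels x samples matrix", call. = FALSE)
  check_channel_labels(channel_labels)
  if (nrow(data) != length(channel_labels))
    stop("data has ", nrow(data), " rows but ", length(channel_labels),
         " channel labels", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("'rate' must be a single positive number", call. = FALSE)
  if (any(!is.finite(data)))
    stop("recording contains non-finite samples", call. = FALSE)
  rownames(data) <- channel_labels
  structure(list(data = data, rate = rate,
                 channel_labels = channel_labels,
                 subject_id = as.character(subject_id),
                 condition = as.character(condition)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data),
              x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

#' Construct a band-limited signal block
#'
#' Output of the band-decomposition stage: one channels-by-samples matrix
#' confined (nominally) to a single canonical EEG band.
#'
#' @param data Numeric matrix, channels x samples.
#' @param band Band name (`"delta"`, `"theta"`, `"alpha"`, `"beta"`).
#' @param rate Sampling rate in Hz.
#' @param channel_labels Channel labels in source order.
#' @return An object of class `"band_signals"` carrying `nominal_edges`.
#' @export
band_signals <- function(data, band, rate,
                         channel_labels = rownames(data)) {
  check_band(band)
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric matrix", call. = FALSE)
  if (is.null(channel_labels))
    stop("channel labels are required", call. = FALSE)
  rownames(data) <- channel_labels
  structure(list(data = data, band = band,
                 nominal_edges = band_edges(band), rate = rate,
                 channel_labels = channel_labels),
            class = "band_signals")
}

#' @export
print.band_signals <- function(x, ...) {
  cat(sprintf("<band_signals> %s (%g-%g Hz): %d channels x %d samples @ %g Hz\n",
              x$band, x$nominal_edges[1], x$nominal_edges[2],
              nrow(x$data), ncol(x$data), x$rate))
  invisible(x)
}

#' Write an EEG recording as plain CSV
#'
#' Samples-by-channels layout with a header row of channel labels; the
#' sampling rate, subject and condition are stored in a sidecar JSON file
#' (`<path>.meta.json`) so the recording round-trips losslessly.
#'
#' @param rec An [eeg_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(rate = rec$rate, subject_id = rec$subject_id,
               condition = rec$condition,
               channel_labels = rec$channel_labels)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an EEG recording from plain CSV
#'
#' Counterpart of [write_eeg_csv()].  If the sidecar JSON is missing, the
#' rate must be supplied and the subject/condition default to the file name.
#'
#' @param path CSV path (samples x channels with header row).
#' @param rate Sampling rate override (Hz); required without sidecar.
#' @param subject_id,condition Optional overrides.
#' @return An [eeg_recording()].
#' @export
read_eeg_csv <- function(path, rate = NULL, subject_id = NULL,
                         condition = NULL) {
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  rate <- rate %||% meta$rate
  if (is.null(rate))
    stop("no sampling rate: supply 'rate' or provide ", meta_path,
         call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  eeg_recording(t(as.matrix(df)), rate = rate,
                channel_labels = names(df),
                subject_id = subject_id %||% meta$subject_id %||%
                  tools::file_path_sans_ext(basename(path)),
                condition = condition %||% meta$condition %||% "pre")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
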