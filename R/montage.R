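#' The 16-channel 10-20 montage used throughout the package
#'
#' Channel labels, in canonical order, of the 16-electrode international
#' 10-20 montage the pipeline assumes: FP1, FP2, F3, F4 (frontal); F7, T3,
#' T5 (left temporal); F8, T4, T6 (right temporal); C3, C4, P3, P4
#' (parietal); O1, O2 (occipital).
#'
#' @return Character vector of 16 channel labels.
#' @export
#' @examples
#' montage_channels()
montage_channels <- function() {
  c("FP1", "FP2", "F3", "F4",
    "F7", "T3", "T5", "F8", "T4", "T6",
    "C3", "C4", "P3", "P4",
    "O1", "O2")
}

#' Channel-to-lobe assignment for the 16-channel montage
#'
#' Left and right temporal channels are pooled into a single temporal lobe,
#' so nodal metrics aggregate over four regions: frontal (4 channels),
#' temporal (6), parietal (4) and occipital (2).
#'
#' @return Named character vector mapping each channel label to one of
#'   `"frontal"`, `"temporal"`, `"parietal"`, `"occipital"`.
#' @export
montage_lobes <- function() {
  c(FP1 = "frontal", FP2 = "frontal", F3 = "frontal", F4 = "frontal",
    F7 = "temporal", T3 = "temporal", T5 = "temporal",
    F8 = "temporal", T4 = "temporal", T6 = "temporal",
    C3 = "parietal", C4 = "parietal", P3 = "parietal", P4 = "parietal",
    O1 = "occipital", O2 = "occipital")
}

#' Nominal frequency-band edges (Hz)
#'
#' The four canonical EEG bands used by every stage: delta 1-4 Hz, theta
#' 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz.
#'
#' @param band Optional band name; if given, returns its `c(lower, upper)`
#'   edges, otherwise the full named list.
#' @return A named list of length-2 numeric vectors, or one such vector.
#' @export
#' @examples
#' band_edges("theta")
band_edges <- function(band = NULL) {
  edges <- list(delta = c(1, 4), theta = c(4, 8),
                alpha = c(8, 13), beta = c(13, 30))
  if (is.null(band)) return(edges)
  check_band(band)
  edges[[band]]
}

band_names <- function() c("delta", "theta", "alpha", "beta")

check_band <- function(band) {
  if (!(is.character(band) && length(band) == 1L && band %in% band_names()))
    stop("'band' must be one of: ", paste(band_names(), collapse = ", "),
         call. = FALSE)
  invisible(band)
}

check_channel_labels <- function(labels) {
  montage <- montage_channels()
  if (length(labels) != 16L || anyDuplicated(labels) ||
      !all(labels %in% montage))
    stop("channel labels must be the 16 unique 10-20 montage labels; ",
         "offending: ",
         paste(setdiff(labels, montage), collapse = ", "), call. = FALSE)
  invisible(labels)
}
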