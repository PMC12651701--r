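# Signal-conditioning chain: polyphase-style downsampling (zero-phase
# anti-alias low-pass + resampling), zero-phase IIR notch, and a 5-level
# periodized Daubechies-4 discrete wavelet transform whose detail shells
# map onto the four canonical EEG bands at 128 Hz.

# db4 analysis filters (8 taps, 4 vanishing moments).
DB4_LO <- c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
            -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965)
DB4_HI <- c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
            -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
            -0.0328830116668852, -0.010597401785069032)

#' Downsample a recording
#'
#' Zero-phase order-8 Butterworth anti-alias low-pass with cutoff at 0.9x
#' the target Nyquist, followed by cubic-spline resampling onto the new
#' sample grid.  Output length is `floor(n * target_rate / rate)`.
#'
#' @param rec An [eeg_recording()].
#' @param target_rate Target rate in Hz (default 128); upsampling is
#'   refused.
#' @return The downsampled [eeg_recording()] (identity when
#'   `target_rate == rec$rate`).
#' @export
downsample <- function(rec, target_rate = 128) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_rate > rec$rate)
    stop("target_rate (", target_rate, ") exceeds recording rate (",
         rec$rate, "): upsampling is not supported", call. = FALSE)
  if (target_rate == rec$rate) return(rec)
  n0 <- ncol(rec$data)
  n1 <- floor(n0 * target_rate / rec$rate)
  aa <- signal::butter(8, 0.9 * (target_rate / 2) / (rec$rate / 2),
                       type = "low")
  t0 <- (seq_len(n0) - 1) / rec$rate
  t1 <- (seq_len(n1) - 1) / target_rate
  out <- matrix(0, nrow(rec$data), n1)
  for (i in seq_len(nrow(rec$data))) {
    xf <- signal::filtfilt(aa, rec$data[i, ])
    out[i, ] <- stats::spline(t0, xf, xout = t1)$y
  }
  eeg_recording(out, rate = target_rate,
                channel_labels = rec$channel_labels,
                subject_id = rec$subject_id, condition = rec$condition)
}

#' Notch-filter power-line interference
#'
#' Zero-phase second-order Butterworth band-stop with a 4 Hz stop band
#' centred on `line_freq`, giving well over 20 dB attenuation at the line
#' frequency and under 1 dB change 5 Hz away.
#'
#' @param rec An [eeg_recording()].
#' @param line_freq Line frequency in Hz (default 50); must lie below the
#'   Nyquist frequency.
#' @return The filtered [eeg_recording()].
#' @export
notch_filter <- function(rec, line_freq = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate / 2
  if (line_freq >= nyq)
    stop("line_freq (", line_freq, " Hz) must be below Nyquist (",
         nyq, " Hz)", call. = FALSE)
  bf <- signal::butter(2, c(line_freq - 2, line_freq + 2) / nyq,
                       type = "stop")
  out <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  eeg_recording(out, rate = rec$rate, channel_labels = rec$channel_labels,
                subject_id = rec$subject_id, condition = rec$condition)
}

# One periodized DWT analysis step on the rows of a matrix (channels x
# samples); returns approximation and detail halves.
dwt_step <- function(x) dwt_step_cpp(x, DB4_LO, DB4_HI)

# Inverse of dwt_step (transpose of the orthonormal analysis operator).
idwt_step <- function(a, d) idwt_step_cpp(a, d, DB4_LO, DB4_HI)

dwt_multilevel <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    details[[j]] <- s$d
    a <- s$a
  }
  list(a = a, d = details)
}

# Reconstruct keeping selected detail levels (and optionally the final
# approximation), zeroing everything else; levels above the deepest kept
# coefficient set contribute nothing and are skipped.
dwt_reconstruct <- function(coeffs, keep_d = integer(), keep_a = FALSE) {
  levels <- length(coeffs$d)
  start <- if (keep_a) levels else max(keep_d)
  a <- if (keep_a) coeffs$a
  else matrix(0, nrow(coeffs$a), ncol(coeffs$d[[start]]))
  for (j in start:1) {
    d <- if (j %in% keep_d) coeffs$d[[j]]
    else matrix(0, nrow(coeffs$d[[j]]), ncol(coeffs$d[[j]]))
    a <- idwt_step(a, d)
  }
  a
}

#' Decompose a recording into the four canonical bands (db4 wavelet)
#'
#' Five-level periodized db4 discrete wavelet transform at 128 Hz; band
#' reconstructions by inverse transform of selected coefficient sets:
#' beta <- D2 (16-32 Hz shell), alpha <- D3 (8-16), theta <- D4 (4-8),
#' delta <- D5 + A5 (0-4).  D1 (32-64 Hz) is discarded.  The signal is
#' periodically padded to a multiple of 32 samples and the reconstruction
#' truncated back, so the four bands plus D1 reproduce the input exactly.
#'
#' @param rec An [eeg_recording()] at 128 Hz (the shell-to-band map assumes
#'   it; pass `allow_rate = TRUE` to force another rate onto the same
#'   dyadic map).
#' @param allow_rate Permit rates other than 128 Hz (shell edges then scale
#'   with the rate and no longer match the nominal band edges).
#' @return Named list of four [band_signals()] (`delta`, `theta`, `alpha`,
#'   `beta`).
#' @export
wavelet_band_decompose <- function(rec, allow_rate = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate != 128 && !allow_rate)
    stop("wavelet_band_decompose assumes 128 Hz (got ", rec$rate,
         " Hz); downsample first or set allow_rate = TRUE", call. = FALSE)
  levels <- 5L
  n <- ncol(rec$data)
  block <- 2L^levels
  pad <- (block - n %% block) %% block
  x <- if (pad > 0)
    cbind(rec$data, rec$data[, seq_len(pad), drop = FALSE]) else rec$data
  co <- dwt_multilevel(x, levels)
  keep <- list(delta = list(d = 5L, a = TRUE),
               theta = list(d = 4L, a = FALSE),
               alpha = list(d = 3L, a = FALSE),
               beta  = list(d = 2L, a = FALSE))
  recons <- lapply(keep, function(k)
    dwt_reconstruct(co, keep_d = k$d, keep_a = k$a)[, seq_len(n),
                                                    drop = FALSE])
  out <- lapply(stats::setNames(nm = band_names()), function(b) {
    y <- recons[[b]]
    rownames(y) <- rec$channel_labels
    band_signals(y, b, rec$rate, rec$channel_labels)
  })
  # discarded 32-64 Hz shell, kept so callers can verify reconstruction
  attr(out, "d1") <- dwt_reconstruct(co, keep_d = 1L)[, seq_len(n),
                                                      drop = FALSE]
  out
}

# Squared magnitude response of an order-4 analog-prototype Butterworth
# band-pass at frequencies f (Hz) -- the response of one forward and one
# reverse pass, i.e. zero-phase application.
butter_bp_mag2 <- function(f, edges) {
  w0sq <- edges[1] * edges[2]
  bw <- edges[2] - edges[1]
  ratio <- (f^2 - w0sq) / (bw * pmax(f, .Machine$double.xmin))
  r2 <- ratio * ratio
  out <- 1 / (1 + (r2 * r2)^2)
  out[f <= 0] <- 0
  out
}

#' Decompose a recording with zero-phase band-pass filters
#'
#' Alternative to [wavelet_band_decompose()] that confines each band to
#' its exact nominal edges (1-4, 4-8, 8-13, 13-30 Hz) with a zero-phase
#' order-4 Butterworth band-pass (applied forward and reverse in the
#' frequency domain, so filtering is circular; negligible for recordings
#' much longer than a band cycle), for when shell-edge mismatch of the
#' dyadic wavelet map is unacceptable.
#'
#' @param rec An [eeg_recording()]; rate must exceed twice the highest band
#'   edge (60 Hz).
#' @return Named list of four [band_signals()].
#' @export
fir_band_decompose <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate < 60)
    stop("rate must be at least 60 Hz for the 13-30 Hz band", call. = FALSE)
  n <- ncol(rec$data)
  f <- (0:(n - 1)) * rec$rate / n
  f <- pmin(f, rec$rate - f)
  X <- stats::mvfft(t(rec$data))
  lapply(stats::setNames(nm = band_names()), function(b) {
    h2 <- butter_bp_mag2(f, band_edges(b))
    y <- t(Re(stats::mvfft(X * h2, inverse = TRUE)) / n)
    rownames(y) <- rec$channel_labels
    band_signals(y, b, rec$rate, rec$channel_labels)
  })
}

#' Per-band amplitude envelopes of a conditioned recording
#'
#' Convenience front-end producing the four bands' Hilbert amplitude
#' envelopes directly from a (downsampled, notch-filtered) recording.
#' `"wavelet"` reconstructs the band signals via [wavelet_band_decompose()]
#' and applies [amplitude_envelope()]; `"fir"` fuses the exact-edge
#' zero-phase band-pass and the analytic transform into a single spectral
#' pass per band.
#'
#' @param rec An [eeg_recording()].
#' @param band_mode `"wavelet"` (default) or `"fir"`.
#' @return Named list of four `"envelope_matrix"` objects.
#' @export
band_envelopes <- function(rec, band_mode = c("wavelet", "fir")) {
  band_mode <- match.arg(band_mode)
  if (band_mode == "wavelet")
    return(lapply(wavelet_band_decompose(rec), amplitude_envelope))
  n <- ncol(rec$data)
  f <- (0:(n - 1)) * rec$rate / n
  ffold <- pmin(f, rec$rate - f)
  h <- numeric(n)                       # analytic-signal doubling
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  X <- stats::mvfft(t(rec$data))
  lapply(stats::setNames(nm = band_names()), function(b) {
    h2 <- butter_bp_mag2(ffold, band_edges(b))
    env <- t(Mod(stats::mvfft(X * (h2 * h), inverse = TRUE) / n))
    rownames(env) <- rec$channel_labels
    structure(list(data = env, band = b, rate = rec$rate,
                   channel_labels = rec$channel_labels),
              class = "envelope_matrix")
  })
}

#' Run the full signal-conditioning chain
#'
#' Downsample to `target_rate`, notch out the line frequency, then
#' decompose into the four canonical bands.  Artifact removal (ICA,
#' segment rejection) is not performed: the chain expects pre-cleaned
#' data and says so once per session.
#'
#' @param rec An [eeg_recording()].
#' @param target_rate Rate after downsampling (default 128 Hz).
#' @param line_freq Notch frequency (default 50 Hz); `NULL` skips the
#'   notch (e.g. when already below Nyquist).
#' @param band_mode `"wavelet"` (db4 shells, default) or `"fir"`
#'   (zero-phase band-pass at nominal edges).
#' @return Named list of four [band_signals()].
#' @export
preprocess <- function(rec, target_rate = 128, line_freq = 50,
                       band_mode = c("wavelet", "fir")) {
  band_mode <- match.arg(band_mode)
  rec <- downsample(rec, target_rate)
  if (!is.null(line_freq) && line_freq < rec$rate / 2)
    rec <- notch_filter(rec, line_freq)
  if (band_mode == "wavelet") wavelet_band_decompose(rec)
  else fir_band_decompose(rec)
}
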