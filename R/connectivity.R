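# Static functional connectivity: Hilbert amplitude envelopes, low-order
# networks (absolute Pearson correlation between envelopes) and high-order
# networks (absolute Pearson correlation between Fisher-z-transformed
# connectivity profiles).

#' Construct a connectivity matrix object
#'
#' @param weights Symmetric N x N numeric matrix with zero diagonal and
#'   entries in `[0, 1]`.
#' @param order `"low"` (envelope correlations) or `"high"` (profile
#'   correlations).
#' @param band Band name, or `NA` for band-agnostic matrices.
#' @param channel_labels Node labels (defaults to the weight matrix's
#'   rownames).
#' @return An object of class `"connectivity_matrix"`.
#' @export
connectivity_matrix <- function(weights, order = c("low", "high"),
                                band = NA_character_,
                                channel_labels = rownames(weights)) {
  order <- match.arg(order)
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("'weights' must be a square matrix", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-10)
    stop("'weights' must be symmetric", call. = FALSE)
  if (any(diag(weights) != 0))
    stop("diagonal must be zero", call. = FALSE)
  if (min(weights) < -1e-12 || max(weights) > 1 + 1e-12)
    stop("weights must lie in [0, 1]", call. = FALSE)
  if (is.null(channel_labels))
    channel_labels <- paste0("n", seq_len(nrow(weights)))
  dimnames(weights) <- list(channel_labels, channel_labels)
  structure(list(weights = weights, order = order, band = band,
                 channel_labels = channel_labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s-order, band %s, %d nodes, mean %.4f\n",
              x$order, x$band, nrow(x$weights), mean_connectivity(x)))
  invisible(x)
}

# Magnitude of the FFT-based analytic signal, rows of a matrix.
analytic_envelope <- function(x) {
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  X <- stats::mvfft(t(x)) * h
  t(Mod(stats::mvfft(X, inverse = TRUE) / n))
}

#' Amplitude envelope of band-limited signals
#'
#' Per-channel magnitude of the analytic (Hilbert-transformed) signal.  The
#' segment must contain at least two full cycles of the band's lower edge
#' for the analytic signal to be meaningful.
#'
#' @param bs A [band_signals()] object.
#' @return An object of class `"envelope_matrix"` with fields `data`
#'   (channels x samples, non-negative), `band`, `rate`, `channel_labels`.
#' @export
amplitude_envelope <- function(bs) {
  stopifnot(inherits(bs, "band_signals"))
  min_n <- ceiling(2 / bs$nominal_edges[1] * bs$rate)
  if (ncol(bs$data) < min_n)
    stop("segment too short for ", bs$band, " envelope: need >= ", min_n,
         " samples (two cycles of ", bs$nominal_edges[1], " Hz at ",
         bs$rate, " Hz), got ", ncol(bs$data), call. = FALSE)
  env <- analytic_envelope(bs$data)
  rownames(env) <- bs$channel_labels
  structure(list(data = env, band = bs$band, rate = bs$rate,
                 channel_labels = bs$channel_labels),
            class = "envelope_matrix")
}

#' Low-order functional connectivity (LOFC)
#'
#' Absolute Pearson correlation between every pair of channel amplitude
#' envelopes; the diagonal is forced to zero.
#'
#' @param env An `"envelope_matrix"` from [amplitude_envelope()], or a
#'   plain channels x samples matrix.
#' @param band Band tag used when `env` is a plain matrix.
#' @return A `"connectivity_matrix"` with `order = "low"`.
#' @export
compute_lofc <- function(env, band = NULL) {
  if (inherits(env, "envelope_matrix")) {
    band <- band %||% env$band
    labels <- env$channel_labels
    x <- env$data
  } else {
    x <- env
    labels <- rownames(env)
  }
  if (ncol(x) < 3L)
    stop("need at least 3 samples for a correlation", call. = FALSE)
  # two-pass centred cross-product (equivalent to cor, no transposition)
  xc <- x - rowMeans(x)
  cp <- tcrossprod(xc)
  v <- diag(cp)
  if (any(v <= 0))
    stop("zero-variance channel(s): ",
         paste((labels %||% seq_len(nrow(x)))[v <= 0], collapse = ", "),
         call. = FALSE)
  w <- pmin(abs(cp) / sqrt(outer(v, v)), 1)
  diag(w) <- 0
  w <- (w + t(w)) / 2
  connectivity_matrix(w, order = "low", band = band %||% NA_character_,
                      channel_labels = labels)
}

#' Fisher z-transform of a correlation coefficient
#'
#' `z = arctanh(r)`, variance-stabilizing correlations toward normality.
#' Values with `|r| >= 1 - 1e-7` are clipped to `1 - 1e-7` in magnitude so
#' perfect correlations map to a finite value (about 8.4).
#'
#' @param r Numeric vector/matrix of correlations in `[-1, 1]`.
#' @return Transformed values, same shape as `r`.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)))
    stop("non-finite correlation passed to fisher_z", call. = FALSE)
  if (any(abs(r) > 1))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  clip <- 1 - 1e-7
  atanh(pmax(pmin(r, clip), -clip))
}

#' High-order functional connectivity (HOFC)
#'
#' Correlation between nodes' whole connectivity profiles: for each node
#' pair (i, j), take columns i and j of the Fisher-z-transformed low-order
#' matrix, delete rows i and j from both (aligning the remaining N - 2
#' entries by node identity), and store the absolute Pearson correlation.
#'
#' @param lofc A `"connectivity_matrix"` with `order = "low"` and at least
#'   4 nodes.
#' @return A `"connectivity_matrix"` with `order = "high"`.
#' @export
compute_hofc <- function(lofc) {
  stopifnot(inherits(lofc, "connectivity_matrix"))
  if (lofc$order != "low")
    stop("compute_hofc expects a low-order matrix", call. = FALSE)
  n <- nrow(lofc$weights)
  if (n < 4L)
    stop("HOFC needs at least 4 nodes (fewer than 2 residual profile ",
         "entries otherwise)", call. = FALSE)
  z <- fisher_z(lofc$weights)
  diag(z) <- 0
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      keep <- setdiff(seq_len(n), c(i, j))
      w[i, j] <- w[j, i] <- abs(stats::cor(z[keep, i], z[keep, j]))
    }
  connectivity_matrix(w, order = "high", band = lofc$band,
                      channel_labels = lofc$channel_labels)
}

#' Mean connectivity strength
#'
#' Mean of the N(N-1)/2 upper-triangle off-diagonal weights.
#'
#' @param cm A `"connectivity_matrix"`.
#' @return Scalar in `[0, 1]`.
#' @export
mean_connectivity <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  mean(cm$weights[upper.tri(cm$weights)])
}

#' Write / read a connectivity matrix
#'
#' CSV stores the weights with labels as header row and first column; JSON
#' stores a `{order, band, labels, weights}` bundle.  Both round-trip
#' losslessly (JSON at full double precision).
#'
#' @param cm A `"connectivity_matrix"`.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- as.data.frame(cm$weights)
    utils::write.csv(cbind(channel = cm$channel_labels, df), path,
                     row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(list(order = cm$order, band = cm$band,
                              labels = cm$channel_labels,
                              weights = cm$weights),
                         path, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  } else stop("unsupported extension: ", ext, call. = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @param order,band Tags used when reading CSV (which stores only
#'   weights).
#' @export
read_connectivity <- function(path, order = "low", band = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    labels <- df$channel
    w <- as.matrix(df[, -1, drop = FALSE])
    connectivity_matrix(unname(w), order = order, band = band,
                        channel_labels = labels)
  } else if (ext == "json") {
    b <- jsonlite::read_json(path, simplifyVector = TRUE)
    connectivity_matrix(b$weights, order = b$order,
                        band = b$band %||% NA_character_,
                        channel_labels = b$labels)
  } else stop("unsupported extension: ", ext, call. = FALSE)
}
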