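# Dynamic functional networks: non-overlapping windowed connectivity, a
# GE-median integrated/segregated state classifier, transition-pattern
# probabilities over consecutive state pairs, and normalized state entropy.

#' Shortest window length for a band ("1/fmin")
#'
#' Reciprocal of the band's lower edge: delta 1 s, theta 0.25 s, alpha
#' 0.125 s, beta 1/13 s.  (A reading based on the band's centre frequency
#' is available via `rule = "center"`.)
#'
#' @param band Band name.
#' @param rule `"lower"` (default) or `"center"`.
#' @return Window duration in seconds.
#' @export
fmin_window <- function(band, rule = c("lower", "center")) {
  rule <- match.arg(rule)
  e <- band_edges(band)
  if (rule == "lower") 1 / e[1] else 2 / (e[1] + e[2])
}

#' The standard per-band window set
#'
#' The seven non-overlapping window lengths evaluated per band: 1/fmin
#' (see [fmin_window()]) plus 1, 2, 4, 6, 8 and 10 s.
#'
#' @param band Band name.
#' @return Numeric vector of seven window durations in seconds.
#' @export
window_lengths <- function(band) {
  c(fmin_window(band), 1, 2, 4, 6, 8, 10)
}

#' Cut a signal block into non-overlapping windows
#'
#' Consecutive slices of exactly `floor(length_s * rate)` samples; the
#' trailing partial window is discarded.
#'
#' @param x A [band_signals()], `"envelope_matrix"`, or plain channels x
#'   samples matrix.
#' @param length_s Window duration in seconds.
#' @param rate Sampling rate (taken from `x` when it carries one).
#' @return List of channels x window-samples matrices.
#' @export
segment_windows <- function(x, length_s, rate = NULL) {
  if (is.list(x) && !is.null(x$rate)) { rate <- x$rate; x <- x$data }
  stopifnot(is.matrix(x), !is.null(rate))
  wlen <- floor(length_s * rate)
  if (wlen < 2L)
    stop("window of ", length_s, " s holds fewer than 2 samples at ",
         rate, " Hz", call. = FALSE)
  n_win <- ncol(x) %/% wlen
  if (n_win < 2L)
    stop("fewer than 2 complete windows (", n_win,
         "): no state transitions computable", call. = FALSE)
  lapply(seq_len(n_win), function(k)
    x[, ((k - 1L) * wlen + 1L):(k * wlen), drop = FALSE])
}

#' Per-window connectivity matrices
#'
#' One low-order (and optionally high-order) network per window.  Windows
#' are slices of the full-recording amplitude envelope; windows shorter
#' than the envelope's two-cycle precondition are therefore still valid,
#' as the analytic transform was taken on the continuous signal.
#'
#' @param env An `"envelope_matrix"` for the band.
#' @param length_s Window duration in seconds.
#' @param order `"low"` or `"high"`.
#' @return List of `"connectivity_matrix"` objects, one per window.
#' @export
windowed_networks <- function(env, length_s, order = c("low", "high")) {
  order <- match.arg(order)
  stopifnot(inherits(env, "envelope_matrix"))
  wins <- segment_windows(env$data, length_s, env$rate)
  lapply(wins, function(w) {
    lofc <- compute_lofc(w, band = env$band)
    lofc$channel_labels <- env$channel_labels
    dimnames(lofc$weights) <- list(env$channel_labels, env$channel_labels)
    if (order == "low") lofc else compute_hofc(lofc)
  })
}

# Global efficiency of each matrix in a list, batched through igraph by
# stacking windows into one block-diagonal graph (distances between blocks
# are infinite and ignored).
ge_sequence <- function(mats, chunk = 40L) {
  n_nodes <- nrow(mats[[1]]$weights)
  out <- numeric(length(mats))
  idx <- split(seq_along(mats), (seq_along(mats) - 1L) %/% chunk)
  for (grp in idx) {
    k <- length(grp)
    adj <- matrix(0, k * n_nodes, k * n_nodes)
    for (m in seq_len(k)) {
      len <- weights_to_lengths(mats[[grp[m]]])
      len[!is.finite(len)] <- 0
      rng <- ((m - 1L) * n_nodes + 1L):(m * n_nodes)
      adj[rng, rng] <- len
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    d <- igraph::distances(g, algorithm = "dijkstra")
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    for (m in seq_len(k)) {
      rng <- ((m - 1L) * n_nodes + 1L):(m * n_nodes)
      out[grp[m]] <- sum(inv[rng, rng]) / (n_nodes * (n_nodes - 1))
    }
  }
  out
}

#' Classify windows as integrated (1) or segregated (0)
#'
#' Parameter-free median split: a window is integrated iff its global
#' efficiency strictly exceeds the median GE across all windows of the
#' recording (same band, order and window length); ties and values at or
#' below the median are segregated.  If every window has identical GE the
#' sequence is all zeros and a warning is emitted.
#'
#' @param mats List of per-window `"connectivity_matrix"` objects, or a
#'   numeric vector of precomputed per-window GE values.
#' @return Integer vector of 0/1 states with attribute `"ge"` (the
#'   per-window GE) of class `"state_sequence"`.
#' @export
classify_states <- function(mats) {
  ge <- if (is.numeric(mats)) mats else ge_sequence(mats)
  if (length(ge) < 2L)
    stop("need at least 2 windows to classify states", call. = FALSE)
  if (max(ge) - min(ge) <= 0) {
    warning("all windows have identical global efficiency; ",
            "every state labeled segregated (0)")
    states <- rep(0L, length(ge))
  } else {
    states <- as.integer(ge > stats::median(ge))
  }
  structure(states, ge = ge, class = "state_sequence")
}

#' Transition-pattern distribution of a binary state sequence
#'
#' Consecutive state pairs (sliding step 1, so n - 1 pairs) are read as
#' the four patterns 00, 01, 10, 11; probabilities are pair counts over
#' n - 1.
#'
#' @param states Binary (0/1) state vector of length >= 2 (a
#'   `"state_sequence"` or plain vector).
#' @return Named numeric vector `c(p00, p01, p10, p11)` summing to 1, with
#'   attribute `"n_pairs"`.
#' @export
transition_patterns <- function(states) {
  states <- as.integer(unclass(states))
  n <- length(states)
  if (n < 2L) stop("need at least 2 states", call. = FALSE)
  if (!all(states %in% c(0L, 1L)))
    stop("states must be 0/1", call. = FALSE)
  pair <- 2L * states[-n] + states[-1L]           # 0..3 = 00,01,10,11
  counts <- tabulate(pair + 1L, nbins = 4L)
  p <- counts / (n - 1L)
  names(p) <- c("p00", "p01", "p10", "p11")
  attr(p, "n_pairs") <- n - 1L
  p
}

#' Normalized state entropy (NSE)
#'
#' `NSE = -(1/log M) * sum_i p_i log p_i` over the M = 4 transition
#' patterns, with `0 log 0 = 0`; lies in `[0, 1]`, reaching 1 for the
#' uniform distribution and 0 for a degenerate one.  The log base cancels.
#'
#' @param p Probability vector over the four patterns (any non-negative
#'   vector summing to 1 within 1e-9).
#' @return Scalar NSE in `[0, 1]`.
#' @export
state_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("'p' must be a probability distribution (sum 1 within 1e-9)",
         call. = FALSE)
  m <- length(p)
  nz <- p[p > 0]
  -sum(nz * log(nz)) / log(m) + 0   # + 0 normalizes IEEE negative zero
}

#' Dynamic-network state entropy across the standard window set
#'
#' For one band envelope: builds per-window networks at each of the seven
#' window lengths, classifies integrated/segregated states by the
#' GE-median rule, and returns the transition-pattern distribution and
#' normalized state entropy per window length.
#'
#' @param env An `"envelope_matrix"` for the band.
#' @param order `"low"` or `"high"`.
#' @param lengths_s Window durations in seconds (default
#'   [window_lengths()] for the band).
#' @return Data frame: band, order, window_length_s, n_windows, p00, p01,
#'   p10, p11, NSE.
#' @export
dynamic_entropy <- function(env, order = c("low", "high"),
                            lengths_s = window_lengths(env$band)) {
  order <- match.arg(order)
  rows <- lapply(lengths_s, function(L) {
    mats <- windowed_networks(env, L, order)
    states <- classify_states(mats)
    p <- transition_patterns(states)
    data.frame(band = env$band, order = order, window_length_s = L,
               n_windows = length(states),
               p00 = p[["p00"]], p01 = p[["p01"]],
               p10 = p[["p10"]], p11 = p[["p11"]],
               NSE = state_entropy(p))
  })
  do.call(rbind, rows)
}
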