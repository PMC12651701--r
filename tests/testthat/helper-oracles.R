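# Independent brute-force oracles used to validate the implementation.

# Two-pass covariance-formula Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# All-pairs shortest paths by triple-loop Floyd-Warshall.
oracle_floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Nodal efficiency directly from the distance matrix definition.
oracle_nodal_efficiency <- function(d) {
  n <- nrow(d)
  sapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(d[i, j]))
      s <- s + 1 / d[i, j]
    s / (n - 1)
  })
}

# Zhang-Horvath weighted clustering by explicit triple loop.
oracle_ncc_zhang <- function(w) {
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    num <- 0
    for (j in seq_len(n)) for (k in seq_len(n))
      if (j != i && k != i && j != k)
        num <- num + w[i, j] * w[j, k] * w[k, i]
    s1 <- sum(w[i, -i])
    s2 <- sum(w[i, -i]^2)
    if (s1^2 - s2 > 0) num / (s1^2 - s2) else 0
  })
}

# HOFC by explicitly forming both reduced profile columns.
oracle_hofc <- function(lofc_w) {
  n <- nrow(lofc_w)
  z <- atanh(pmin(pmax(lofc_w, -(1 - 1e-7)), 1 - 1e-7))
  diag(z) <- 0
  h <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    keep <- setdiff(seq_len(n), c(i, j))
    h[i, j] <- h[j, i] <- abs(oracle_pearson(z[keep, i], z[keep, j]))
  }
  h
}

# Random symmetric weight matrix with zero diagonal.
rand_weight_matrix <- function(n, values = NULL) {
  w <- matrix(0, n, n)
  m <- n * (n - 1) / 2
  x <- if (is.null(values)) runif(m) else sample(values, m, replace = TRUE)
  w[upper.tri(w)] <- x
  w <- w + t(w)
  w
}

# Single-channel-replicated recording from a waveform.
tone_recording <- function(x, rate, nch = 16) {
  eeg_recording(matrix(rep(x, each = nch), nch), rate = rate)
}

# Band power via FFT in a frequency window.
spectral_power <- function(x, rate, f0, halfwidth = 0.5) {
  n <- length(x)
  fr <- (0:(n - 1)) * rate / n
  X <- Mod(stats::fft(x))^2
  sum(X[abs(fr - f0) < halfwidth | abs((rate - fr) - f0) < halfwidth])
}
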