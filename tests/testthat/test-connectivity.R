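test_that("amplitude envelope tracks constant and modulated tones", {
  rate <- 128
  t0 <- (seq_len(8 * rate) - 1) / rate
  bs <- band_signals(matrix(2 * sin(2 * pi * 10 * t0), 1,
                            dimnames = list("A", NULL)),
                     "alpha", rate)
  env <- amplitude_envelope(bs)$data[1, ]
  interior <- env[rate:(length(env) - rate)]
  expect_lt(max(abs(interior - 2)) / 2, 0.05)
  # AM tone: envelope follows the modulator
  am <- (1 + 0.5 * cos(2 * pi * 1 * t0)) * cos(2 * pi * 10 * t0)
  bs <- band_signals(matrix(am, 1, dimnames = list("A", NULL)), "alpha", rate)
  env <- amplitude_envelope(bs)$data[1, ]
  target <- 1 + 0.5 * cos(2 * pi * 1 * t0)
  idx <- rate:(length(env) - rate)
  expect_lt(sqrt(mean((env[idx] - target[idx])^2)) / sqrt(mean(target^2)),
            0.05)
  # zero in, zero out; short segments are refused with the minimum length
  zs <- band_signals(matrix(0, 1, 8 * rate, dimnames = list("A", NULL)),
                     "alpha", rate)
  expect_true(all(amplitude_envelope(zs)$data == 0))
  short <- band_signals(matrix(rnorm(10), 1, dimnames = list("A", NULL)),
                        "delta", rate)
  expect_error(amplitude_envelope(short), "256")
})

test_that("low-order connectivity is the absolute envelope correlation", {
  x <- rbind(a = c(1, 2, 3, 4, 5, 6),
             b = c(2, 4, 6, 8, 10, 12),       # identical profile up to gain
             c = c(6, 5, 4, 3, 2, 1),         # perfect anticorrelation
             d = c(1, 3, 2, 5, 4, 6))
  cm <- compute_lofc(x, band = "delta")
  expect_equal(cm$weights["a", "b"], 1)
  expect_equal(cm$weights["a", "c"], 1)       # |r| of r = -1
  expect_true(all(diag(cm$weights) == 0))
  # brute-force covariance-formula oracle
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(cm$weights[i, j], abs(oracle_pearson(x[i, ], x[j, ])),
                 tolerance = 1e-12)
  expect_error(compute_lofc(x[, 1:2]), "3 samples")
  x["d", ] <- 7
  expect_error(compute_lofc(x), "zero-variance.*d")
})

test_that("low-order connectivity is invariant to positive affine rescaling", {
  set.seed(20)
  x <- matrix(abs(rnorm(5 * 200)), 5)
  rownames(x) <- paste0("n", 1:5)
  gains <- runif(5, 0.5, 3)
  offsets <- rnorm(5)
  y <- x * gains + offsets
  expect_equal(compute_lofc(x)$weights, compute_lofc(y)$weights,
               tolerance = 1e-12)
})

test_that("the Fisher z-transform is exact, odd, monotone and clipped", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5), tolerance = 1e-12)
  z1 <- fisher_z(1)
  expect_true(is.finite(z1))
  expect_equal(z1, atanh(1 - 1e-7), tolerance = 1e-12)
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(NaN), "non-finite")
  expect_error(fisher_z(1.5), "\\[-1, 1\\]")
})

test_that("high-order connectivity matches the explicit profile oracle", {
  set.seed(21)
  w <- rand_weight_matrix(6)
  rownames(w) <- colnames(w) <- paste0("n", 1:6)
  lofc <- connectivity_matrix(w, order = "low")
  hofc <- compute_hofc(lofc)
  expect_equal(unname(hofc$weights), oracle_hofc(w), tolerance = 1e-12)
  expect_identical(hofc$order, "high")
  expect_error(compute_hofc(hofc), "low-order")
  expect_error(compute_hofc(connectivity_matrix(rand_weight_matrix(3),
                                                order = "low")),
               "4 nodes")
})

test_that("duplicated and orthogonalized profiles hit the HOFC extremes", {
  set.seed(22)
  # nodes 1 and 2 with identical connectivity to all other nodes
  w <- rand_weight_matrix(6)
  w[1, 3:6] <- w[2, 3:6] <- runif(4)
  w[3:6, 1] <- w[1, 3:6]; w[3:6, 2] <- w[2, 3:6]
  w[1, 2] <- w[2, 1] <- 0.5
  hofc <- compute_hofc(connectivity_matrix(w, order = "low"))
  expect_equal(unname(hofc$weights[1, 2]), 1, tolerance = 1e-12)
  # 5-node matrix with node 2's profile orthogonalized against node 1's
  # over the 3 shared rows (after Fisher z, centred)
  repeat {
    w <- rand_weight_matrix(5)
    z <- atanh(w); diag(z) <- 0
    a <- z[3:5, 1]; b <- z[3:5, 2]
    ac <- a - mean(a)
    bo <- b - sum((b - mean(b)) * ac) / sum(ac^2) * ac
    r <- tanh(bo + mean(b))
    if (all(r > 0 & r < 1)) break
  }
  w[3:5, 2] <- w[2, 3:5] <- r
  hofc <- compute_hofc(connectivity_matrix(w, order = "low"))
  expect_lt(abs(hofc$weights[1, 2]), 1e-10)
})

test_that("high-order connectivity is equivariant under node relabeling", {
  set.seed(23)
  w <- rand_weight_matrix(7)
  p <- sample(7)
  h <- compute_hofc(connectivity_matrix(w, order = "low"))$weights
  hp <- compute_hofc(connectivity_matrix(w[p, p], order = "low"))$weights
  expect_equal(unname(hp), unname(h[p, p]), tolerance = 1e-12)
})

test_that("mean connectivity averages the upper triangle", {
  w <- matrix(0.5, 3, 3); diag(w) <- 0
  expect_equal(mean_connectivity(connectivity_matrix(w, "low")), 0.5)
  expect_equal(mean_connectivity(connectivity_matrix(matrix(0, 4, 4), "low")),
               0)
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.2
  w[1, 3] <- w[3, 1] <- 0.4
  w[2, 3] <- w[3, 2] <- 0.6
  expect_equal(mean_connectivity(connectivity_matrix(w, "low")), 0.4)
})

test_that("connectivity matrices round-trip through CSV and JSON", {
  set.seed(24)
  w <- rand_weight_matrix(16)
  rownames(w) <- colnames(w) <- montage_channels()
  cm <- connectivity_matrix(w, order = "high", band = "theta")
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "m.json")
  write_connectivity(cm, p1)
  back <- read_connectivity(p1)
  expect_equal(back$weights, cm$weights, tolerance = 1e-12)
  expect_identical(back$order, "high")
  expect_identical(back$band, "theta")
  expect_identical(back$channel_labels, montage_channels())
  p2 <- file.path(dir, "m.csv")
  write_connectivity(cm, p2)
  back2 <- read_connectivity(p2, order = "high", band = "theta")
  expect_equal(unname(back2$weights), unname(cm$weights), tolerance = 1e-12)
})
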