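test_that("downsampling preserves length contract and spectral content", {
  set.seed(1)
  rate0 <- 1000
  dur <- 20
  t0 <- (seq_len(dur * rate0) - 1) / rate0
  rec <- tone_recording(sin(2 * pi * 5 * t0), rate0)
  out <- downsample(rec, 128)
  expect_equal(out$rate, 128)
  expect_true(abs(ncol(out$data) - dur * 128) <= 1)
  expect_identical(out$channel_labels, rec$channel_labels)
  # dominant peak still at 5 Hz
  x <- out$data[1, ]
  fr <- (0:(length(x) - 1)) * 128 / length(x)
  half <- seq_len(length(x) %/% 2)
  peak <- fr[half][which.max(Mod(stats::fft(x))[half])]
  expect_lt(abs(peak - 5), 0.1)
})

test_that("downsampling at the native rate is the identity and upsampling is refused", {
  set.seed(2)
  rec <- tone_recording(rnorm(512), 128)
  expect_identical(downsample(rec, 128), rec)
  expect_error(downsample(rec, 256), "upsampling")
})

test_that("notch filter suppresses the line frequency and little else", {
  rate <- 128
  t0 <- (seq_len(20 * rate) - 1) / rate
  x50 <- sin(2 * pi * 50 * t0)
  x10 <- sin(2 * pi * 10 * t0)
  rec <- tone_recording(x50 + x10, rate)
  out <- notch_filter(rec, 50)
  y <- out$data[1, ]
  expect_gt(spectral_power(x50 + x10, rate, 50) / spectral_power(y, rate, 50),
            100)
  expect_lt(abs(spectral_power(y, rate, 10) /
                  spectral_power(x50 + x10, rate, 10) - 1), 0.1)
  # 5 Hz away the passband is essentially untouched (< 1 dB)
  x45 <- sin(2 * pi * 45 * t0)
  y45 <- notch_filter(tone_recording(x45, rate), 50)$data[1, ]
  expect_gt(mean(y45^2) / mean(x45^2), 10^(-1 / 10))
})

test_that("notch generalizes to 60 Hz and rejects super-Nyquist lines", {
  rate <- 256
  t0 <- (seq_len(20 * rate) - 1) / rate
  x60 <- sin(2 * pi * 60 * t0)
  y <- notch_filter(tone_recording(x60, rate), 60)$data[1, ]
  expect_gt(spectral_power(x60, rate, 60) / spectral_power(y, rate, 60), 100)
  expect_error(notch_filter(tone_recording(x60, rate), 200), "Nyquist")
  zero <- notch_filter(tone_recording(rep(0, 512), 128), 50)
  expect_true(all(zero$data == 0))
})

test_that("wavelet decomposition localizes tones in their nominal bands", {
  rate <- 128
  t0 <- (seq_len(30 * rate) - 1) / rate
  rec <- tone_recording(sin(2 * pi * 6 * t0), rate)
  bands <- wavelet_band_decompose(rec)
  pw <- vapply(bands, function(b) sum(b$data[1, ]^2), 0)
  expect_gt(pw[["theta"]] / sum(pw), 0.7)
  # plurality lands in the right band for a tone near each band centre
  for (ctr in c(delta = 2.5, theta = 6, alpha = 10, beta = 22)) {
    b <- wavelet_band_decompose(tone_recording(sin(2 * pi * ctr * t0), rate))
    pw <- vapply(b, function(x) sum(x$data[1, ]^2), 0)
    expect_identical(names(which.max(pw)),
                     names(which(c(delta = 2.5, theta = 6, alpha = 10,
                                   beta = 22) == ctr)))
  }
})

test_that("wavelet bands plus the discarded shell reconstruct the input", {
  set.seed(3)
  rec <- tone_recording(rnorm(3000), 128)   # length not a multiple of 32
  bands <- wavelet_band_decompose(rec)
  total <- Reduce(`+`, lapply(bands, function(b) b$data)) + attr(bands, "d1")
  rel <- sqrt(sum((total - rec$data)^2) / sum(rec$data^2))
  expect_lt(rel, 1e-8)
  zero <- wavelet_band_decompose(tone_recording(rep(0, 512), 128))
  expect_true(all(vapply(zero, function(b) all(b$data == 0), TRUE)))
  expect_error(wavelet_band_decompose(tone_recording(rnorm(512), 256)),
               "128")
  expect_identical(bands$delta$nominal_edges, c(1, 4))
  expect_identical(bands$beta$nominal_edges, c(13, 30))
})

test_that("the conditioning chain is linear and never permutes channels", {
  set.seed(4)
  x <- matrix(rnorm(16 * 2560), 16)
  rec <- eeg_recording(x, 128)
  rec5 <- eeg_recording(5 * x, 128)
  chain <- function(r) {
    b <- preprocess(r, target_rate = 128, line_freq = 50)
    b$alpha$data
  }
  expect_equal(chain(rec5), 5 * chain(rec), tolerance = 1e-10)
  b <- preprocess(rec, 128, 50)
  expect_identical(rownames(b$theta$data), montage_channels())
})

test_that("exact-edge band mode confines tones to their nominal bands", {
  rate <- 128
  t0 <- (seq_len(30 * rate) - 1) / rate
  rec <- tone_recording(sin(2 * pi * 14 * t0), rate)  # beta, outside D2 shell
  bands <- fir_band_decompose(rec)
  pw <- vapply(bands, function(b) sum(b$data[1, ]^2), 0)
  expect_gt(pw[["beta"]] / sum(pw), 0.9)
  expect_error(fir_band_decompose(tone_recording(rnorm(100), 50)), "60 Hz")
})
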