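test_that("the shortest window is the reciprocal of the band's lower edge", {
  expect_equal(fmin_window("delta"), 1)
  expect_equal(fmin_window("theta"), 0.25)
  expect_equal(fmin_window("alpha"), 0.125)
  expect_equal(fmin_window("beta"), 1 / 13)
  expect_equal(fmin_window("delta", rule = "center"), 2 / 5)
  expect_length(window_lengths("alpha"), 7)
  expect_equal(window_lengths("delta")[-1], c(1, 2, 4, 6, 8, 10))
})

test_that("windowing cuts exact non-overlapping slices and drops the tail", {
  x <- matrix(seq_len(2 * 38400), nrow = 2, byrow = TRUE)
  wins <- segment_windows(x, 2, rate = 128)
  expect_length(wins, 150)                      # 300 s / 2 s
  expect_true(all(vapply(wins, ncol, 0L) == 256))
  expect_identical(wins[[2]][1, 1:3], x[1, 257:259])
  expect_length(segment_windows(x, 10, rate = 128), 30)
  # trailing partial window is discarded
  expect_length(segment_windows(x[, 1:1000, drop = FALSE], 3, rate = 128), 2)
  expect_error(segment_windows(x, 200, rate = 128), "fewer than 2")
  expect_error(segment_windows(x, 0.005, rate = 128), "fewer than 2 samples")
})

test_that("windowed networks are stable under stationary coupling and split by regime", {
  set.seed(40)
  cs <- coupling_spec("alpha", global_coupling = 0.6,
                      within_community_coupling = 0)
  env <- amplitude_envelope(generate_band_sources(cs, 120, 128))
  frob_spread <- function(len) {
    mats <- windowed_networks(env, len, "low")
    ws <- lapply(mats, function(m) m$weights)
    mw <- Reduce(`+`, ws) / length(ws)
    mean(vapply(ws, function(w) sqrt(sum((w - mw)^2)), 0))
  }
  expect_lt(frob_spread(10), frob_spread(2))   # longer windows, less noise
  # a planted regime switch separates window matrices across the switch
  set.seed(41)
  hi <- generate_band_sources(coupling_spec("alpha", 0.9, 0), 60, 128)
  lo <- generate_band_sources(coupling_spec("alpha", 0, 0), 60, 128)
  two <- band_signals(cbind(hi$data, lo$data), "alpha", 128,
                      hi$channel_labels)
  mats <- windowed_networks(amplitude_envelope(two), 10, "low")
  m <- vapply(mats, mean_connectivity, 0)
  expect_gt(min(m[1:6]), max(m[7:12]))
  short <- band_signals(hi$data[, 1:1280], "alpha", 128, hi$channel_labels)
  expect_error(windowed_networks(amplitude_envelope(short), 10),
               "fewer than 2")
})

test_that("the GE-median rule labels high-efficiency windows integrated", {
  expect_identical(as.integer(classify_states(c(0.2, 0.8, 0.2, 0.8))),
                   c(0L, 1L, 0L, 1L))
  expect_warning(st <- classify_states(rep(0.5, 6)), "identical")
  expect_identical(as.integer(st), rep(0L, 6))
  expect_error(classify_states(0.4), "2 windows")
})

test_that("transition patterns enumerate consecutive state pairs", {
  p <- transition_patterns(c(0, 1, 0, 1))
  expect_equal(as.vector(p), c(0, 2 / 3, 1 / 3, 0))
  expect_identical(attr(p, "n_pairs"), 3L)
  expect_equal(as.vector(transition_patterns(c(1, 1, 1))), c(0, 0, 0, 1))
  expect_equal(as.vector(transition_patterns(c(0, 0, 1, 1, 0))),
               rep(0.25, 4))
  expect_error(transition_patterns(1L), "2 states")
  expect_error(transition_patterns(c(0, 2)), "0/1")
  # pattern-count conservation over random sequences
  set.seed(42)
  for (rep in 1:20) {
    s <- sample(0:1, sample(2:50, 1), replace = TRUE)
    p <- transition_patterns(s)
    expect_equal(sum(p) * attr(p, "n_pairs"), length(s) - 1)
  }
})

test_that("normalized state entropy hits its closed forms and bounds", {
  expect_equal(state_entropy(rep(0.25, 4)), 1, tolerance = 1e-15)
  expect_equal(state_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(state_entropy(c(0.5, 0.5, 0, 0)), 0.5, tolerance = 1e-15)
  expect_error(state_entropy(c(0.5, 0.6, 0, 0)), "sum 1")
  set.seed(43)
  for (rep in 1:50) {
    p <- stats::rgamma(4, 1); p <- p / sum(p)
    nse <- state_entropy(p)
    expect_gte(nse, 0)
    expect_lte(nse, 1)
  }
})

test_that("planted constant and alternating regimes yield the expected entropy", {
  # constant regime -> zero entropy regardless of window length
  states <- rep(1L, 30)
  expect_equal(state_entropy(transition_patterns(states)), 0)
  # strict alternation tiled exactly by windows -> only 01/10 patterns
  set.seed(44)
  td <- generate_state_dynamics(epoch_s = 10, duration_s = 100, jitter = 0)
  planted <- td$state
  p <- transition_patterns(planted)
  expect_equal(p[["p00"]], 0)
  expect_equal(p[["p11"]], 0)
  n <- length(planted)
  # enumerated pair distribution of an alternating sequence
  n01 <- sum(planted[-n] == 0 & planted[-1] == 1)
  n10 <- sum(planted[-n] == 1 & planted[-1] == 0)
  expected <- c(0, n01, n10, 0) / (n - 1)
  expect_equal(as.vector(p), expected, tolerance = 1e-15)
  expect_equal(state_entropy(p),
               -sum(expected[expected > 0] * log(expected[expected > 0])) /
                 log(4),
               tolerance = 1e-9)
})

test_that("per-band entropy tables cover the standard window set", {
  set.seed(45)
  cs <- coupling_spec("delta", global_coupling = 0.5,
                      within_community_coupling = 0.2)
  env <- amplitude_envelope(generate_band_sources(cs, 120, 128))
  dyn <- dynamic_entropy(env, "low", lengths_s = c(2, 4))
  expect_identical(nrow(dyn), 2L)
  expect_equal(dyn$n_windows, c(60, 30))
  expect_true(all(dyn$NSE >= 0 & dyn$NSE <= 1))
  expect_equal(dyn$p00 + dyn$p01 + dyn$p10 + dyn$p11, c(1, 1))
})
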