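test_that("coupling specifications are validated", {
  expect_error(coupling_spec("gamma"), "band")
  expect_error(coupling_spec("delta", global_coupling = 1.2), "\\[0, 1\\]")
  expect_error(coupling_spec("delta", global_coupling = 0.7,
                             within_community_coupling = 0.6), "<= 1")
  expect_error(coupling_spec("delta",
                             community_assignment = c(FP1 = "a")),
               "missing channels")
  expect_error(cohort_spec(duration_s = 30), ">= 60")
})

test_that("full global coupling yields identical, perfectly correlated channels", {
  set.seed(10)
  cs <- coupling_spec("alpha", global_coupling = 1,
                      within_community_coupling = 0)
  bs <- generate_band_sources(cs, duration_s = 60, rate = 128)
  expect_true(all(bs$data == matrix(bs$data[1, ], 16, ncol(bs$data),
                                    byrow = TRUE)))
  env <- amplitude_envelope(bs)
  expect_equal(min(stats::cor(t(env$data))), 1)
})

test_that("uncoupled channels have vanishing envelope correlation", {
  # Monte-Carlo over 20 seeds at 300 s
  cs <- coupling_spec("alpha", global_coupling = 0,
                      within_community_coupling = 0)
  mean_abs <- vapply(1:20, function(s) {
    set.seed(s)
    env <- amplitude_envelope(generate_band_sources(cs, 300, 128))
    r <- stats::cor(t(env$data))
    mean(abs(r[upper.tri(r)]))
  }, 0)
  expect_lt(mean(mean_abs), 0.1)
})

test_that("planted communities raise within-block over between-block connectivity", {
  cs <- coupling_spec("theta", global_coupling = 0,
                      within_community_coupling = 0.8)
  comm <- cs$community_assignment
  same <- outer(comm, comm, "==")
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    env <- amplitude_envelope(generate_band_sources(cs, 60, 128))
    w <- compute_lofc(env)$weights
    ut <- upper.tri(w)
    mean(w[ut & same]) > mean(w[ut & !same])
  }, TRUE)
  expect_true(all(wins))
})

test_that("envelope correlation is monotone in the global coupling", {
  grid <- c(0, 0.3, 0.6, 0.9)
  inc <- vapply(1:20, function(s) {
    m <- vapply(grid, function(g) {
      set.seed(s)
      cs <- coupling_spec("alpha", global_coupling = g,
                          within_community_coupling = 0)
      env <- amplitude_envelope(generate_band_sources(cs, 60, 128))
      r <- stats::cor(t(env$data))
      mean(r[upper.tri(r)])
    }, 0)
    all(diff(m) > 0)
  }, TRUE)
  # paired sign test: monotone on essentially every seed
  expect_gte(mean(inc), 0.9)
})

test_that("band sources are spectrally confined to their bands", {
  set.seed(11)
  for (b in c("delta", "theta", "alpha", "beta")) {
    e <- band_edges(b)
    bs <- generate_band_sources(coupling_spec(b), 60, 128)
    x <- bs$data[1, ]
    n <- length(x)
    fr <- (0:(n - 1)) * 128 / n
    fr <- pmin(fr, 128 - fr)
    pw <- Mod(stats::fft(x))^2
    inside <- fr >= 0.5 * e[1] & fr <= 1.5 * e[2]
    expect_gt(sum(pw[inside]) / sum(pw), 0.9)
  }
  expect_error(generate_band_sources(coupling_spec("beta"), 10, rate = 50),
               "2x")
})

test_that("regime timelines alternate with the requested dwell structure", {
  set.seed(12)
  td <- generate_state_dynamics(epoch_s = 50, duration_s = 100, jitter = 0)
  expect_identical(nrow(td), 2L)
  expect_identical(abs(diff(td$state)), 1L)
  expect_equal(td$offset_s - td$onset_s, c(50, 50))
  expect_warning(generate_state_dynamics(200, 100), "single regime")
  td2 <- generate_state_dynamics(10, 100, jitter = 0.2)
  expect_true(all(abs(diff(td2$state)) == 1))
  dw <- (td2$offset_s - td2$onset_s)[-nrow(td2)]
  expect_true(all(dw >= 8 - 1e-9 & dw <= 12 + 1e-9))
})

test_that("cohort generation is deterministic and ledgered", {
  spec <- cohort_spec(n_subjects = 2, duration_s = 60, sampling_rate = 128,
                      seed = 77)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$subjects[[1]]$pre$data, co2$subjects[[1]]$pre$data)
  expect_identical(co1$subjects[[2]]$post$data, co2$subjects[[2]]$post$data)
  # different subjects / conditions differ
  expect_false(identical(co1$subjects[[1]]$pre$data,
                         co1$subjects[[2]]$pre$data))
  expect_false(identical(co1$subjects[[1]]$pre$data,
                         co1$subjects[[1]]$post$data))
  led <- co1$ledger$recordings
  expect_length(led, 4L)
  expect_equal(led$s01_pre$gains$delta$global, 0.55)
  expect_equal(led$s01_post$gains$delta$global, 0.70)
  # default cohort size matches the study design
  expect_identical(cohort_spec()$n_subjects, 28L)
})

test_that("cohorts round-trip through CSV with ledger intact", {
  spec <- cohort_spec(n_subjects = 1, duration_s = 60, sampling_rate = 128,
                      seed = 5)
  co <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(co, dir, format = "csv")
  expect_true(file.exists(file.path(dir, "ledger.json")))
  back <- read_eeg_csv(file.path(dir, "s01_pre.csv"))
  expect_equal(back$data, co$subjects[[1]]$pre$data,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(back$condition, "pre")
  expect_equal(back$rate, 128)
})
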