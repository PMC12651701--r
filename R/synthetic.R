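# Synthetic EEG cohort generator.  Each band-limited source is Gaussian
# white noise shaped by a zero-phase order-4 Butterworth band-pass applied
# in the frequency domain; channels mix a shared (global) source, a
# community source and an independent source, so planted envelope coupling
# is controlled by the mixing weights.  Integrated/segregated regime
# dynamics modulate the global vs community gains over time.

#' Specify planted coupling for one frequency band
#'
#' @param band Band name (`"delta"`, `"theta"`, `"alpha"`, `"beta"`).
#' @param global_coupling Variance fraction in `[0,1]` of the band's
#'   shared source; raises envelope correlation between *all* channel
#'   pairs.
#' @param within_community_coupling Variance fraction in `[0,1]` of the
#'   community source shared by channels with the same community label.
#' @param community_assignment Named character vector channel -> community
#'   label covering all 16 montage channels.  Default splits the montage
#'   into anterior and posterior communities.
#' @param noise_sd Standard deviation (microvolts) of the broadband pink
#'   (1/f) background added before band decomposition.
#' @return A validated `"coupling_spec"` list.
#' @details Couplings are variance fractions: each channel is
#'   `sqrt(g) * shared + sqrt(w) * community + sqrt(1 - g - w) * independent`,
#'   so the two couplings must sum to at most 1 and the inter-channel
#'   *signal* correlation equals the summed shared fractions.  At
#'   `global_coupling = 1` all channels carry the identical signal; at 0/0
#'   channels are independent.
#' @export
coupling_spec <- function(band, global_coupling = 0.5,
                          within_community_coupling = 0.15,
                          community_assignment = default_communities(),
                          noise_sd = 5) {
  check_band(band)
  stopifnot(is.numeric(global_coupling), length(global_coupling) == 1L,
            is.numeric(within_community_coupling),
            length(within_community_coupling) == 1L,
            is.numeric(noise_sd), noise_sd >= 0)
  if (global_coupling < 0 || global_coupling > 1 ||
      within_community_coupling < 0 || within_community_coupling > 1)
    stop("coupling weights must lie in [0, 1]", call. = FALSE)
  if (global_coupling + within_community_coupling > 1)
    stop("global_coupling + within_community_coupling must be <= 1 ",
         "(the remainder is the independent-source weight)", call. = FALSE)
  miss <- setdiff(montage_channels(), names(community_assignment))
  if (length(miss))
    stop("community_assignment missing channels: ",
         paste(miss, collapse = ", "), call. = FALSE)
  structure(list(band = band, global_coupling = global_coupling,
                 within_community_coupling = within_community_coupling,
                 community_assignment =
                   community_assignment[montage_channels()],
                 noise_sd = noise_sd),
            class = "coupling_spec")
}

#' Default anterior/posterior community split of the montage
#' @return Named character vector channel -> `"anterior"`/`"posterior"`.
#' @export
default_communities <- function() {
  ant <- c("FP1", "FP2", "F3", "F4", "F7", "F8")
  ch <- montage_channels()
  stats::setNames(ifelse(ch %in% ant, "anterior", "posterior"), ch)
}

#' Default condition presets for a pre/post cohort
#'
#' Post-condition coupling raises the delta band and lowers theta, alpha
#' and beta relative to pre, the direction the pipeline is expected to
#' recover.  Magnitudes are modelling choices, not fitted values.
#'
#' @return Named list with `pre` and `post`, each a band-named list of
#'   [coupling_spec()] objects.
#' @export
default_coupling_preset <- function() {
  g_pre <- c(delta = 0.55, theta = 0.50, alpha = 0.50, beta = 0.42)
  g_post <- c(delta = 0.70, theta = 0.38, alpha = 0.38, beta = 0.30)
  mk <- function(g) lapply(stats::setNames(nm = band_names()), function(b)
    coupling_spec(b, global_coupling = unname(g[b])))
  list(pre = mk(g_pre), post = mk(g_post))
}

#' Specify a synthetic pre/post cohort
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param conditions Named list of condition -> band -> [coupling_spec()];
#'   default [default_coupling_preset()].
#' @param duration_s Recording length in seconds (>= 60; default 300,
#'   matching a five-minute resting-state protocol).
#' @param sampling_rate Synthesis rate in Hz (default 1000 so the
#'   downsampling stage is exercised; 128 is the fast mode).
#' @param state_epoch_s Mean dwell time (s) of the integrated/segregated
#'   regimes; `NULL` disables regime dynamics (static coupling).
#' @param dwell_jitter Uniform relative jitter on dwell times (default 0.2,
#'   i.e. +/-20%); set 0 for exact epoch tiling.
#' @param amplitude Per-band source RMS amplitude in microvolts.
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   cohorts.
#' @return A validated `"cohort_spec"` list.
#' @export
cohort_spec <- function(n_subjects = 28, conditions = default_coupling_preset(),
                        duration_s = 300, sampling_rate = 1000,
                        state_epoch_s = 10, dwell_jitter = 0.2,
                        amplitude = 10, seed = 1) {
  stopifnot(n_subjects >= 1, sampling_rate > 0, amplitude > 0,
            dwell_jitter >= 0, dwell_jitter < 1)
  if (duration_s < 60)
    stop("duration_s must be >= 60 s", call. = FALSE)
  if (!is.list(conditions) || is.null(names(conditions)) ||
      length(conditions) < 2L)
    stop("'conditions' must be a named list of at least two conditions",
         call. = FALSE)
  for (cond in names(conditions)) {
    bands <- conditions[[cond]]
    if (!setequal(names(bands), band_names()))
      stop("condition '", cond, "' must map all four bands", call. = FALSE)
    for (b in band_names())
      if (!inherits(bands[[b]], "coupling_spec"))
        stop("conditions$", cond, "$", b, " is not a coupling_spec",
             call. = FALSE)
  }
  if (!is.null(state_epoch_s)) stopifnot(state_epoch_s > 0)
  structure(list(n_subjects = as.integer(n_subjects), conditions = conditions,
                 duration_s = duration_s, sampling_rate = sampling_rate,
                 state_epoch_s = state_epoch_s, dwell_jitter = dwell_jitter,
                 amplitude = amplitude, seed = as.integer(seed)),
            class = "cohort_spec")
}

# White Gaussian noise shaped in the frequency domain: bins are drawn as
# Hermitian-symmetric complex Gaussians (the spectrum of white noise),
# multiplied by `mult`, and inverse-transformed, giving real noise with
# amplitude spectrum proportional to `mult`; columns are independent
# series normalized to unit variance.
shaped_noise <- function(n, ncols, mult) {
  half <- n %/% 2L
  thresh <- max(mult) * 1e-6            # bins below carry ~no power
  z <- matrix(0 + 0i, n, ncols)
  if (mult[1] > thresh) z[1, ] <- stats::rnorm(ncols) * mult[1]
  if (n %% 2L == 0L) {
    if (mult[half + 1L] > thresh)
      z[half + 1L, ] <- stats::rnorm(ncols) * mult[half + 1L]
    pos <- 2L:half
  } else {
    pos <- 2L:(half + 1L)
  }
  pos <- pos[mult[pos] > thresh]
  npos <- length(pos)
  z[pos, ] <- matrix(complex(real = stats::rnorm(npos * ncols),
                             imaginary = stats::rnorm(npos * ncols)),
                     npos, ncols) * mult[pos]
  z[n + 2L - pos, ] <- Conj(z[pos, ])
  y <- Re(stats::mvfft(z, inverse = TRUE))
  n_eff <- nrow(y)
  sds <- sqrt((colMeans(y^2) - colMeans(y)^2) * n_eff / (n_eff - 1))
  sweep(y, 2, sds, "/")
}

# Expected standard deviation of un-normalized shaped noise with
# amplitude multipliers `mult` over the full (folded) bin grid.
shaped_noise_sd <- function(n, mult) {
  half <- n %/% 2L
  if (n %% 2L == 0L) {
    v <- mult[1]^2 + mult[half + 1L]^2 + 4 * sum(mult[2L:half]^2)
  } else {
    v <- mult[1]^2 + 4 * sum(mult[2L:(half + 1L)]^2)
  }
  sqrt(v) / n
}

# Zero-phase order-4 Butterworth band-pass magnitude response (applied
# forward and reverse, as filtfilt would) on the folded frequency grid.
band_noise <- function(n, ncols, rate, edges) {
  f <- (0:(n - 1)) * rate / n
  f <- pmin(f, rate - f)                     # fold to [0, Nyquist]
  shaped_noise(n, ncols, butter_bp_mag2(f, edges))
}

# Broadband 1/f ("pink") noise, unit variance per column.
pink_noise <- function(n, ncols, rate) {
  f <- (0:(n - 1)) * rate / n
  f <- pmin(f, rate - f)
  amp <- ifelse(f > 0, 1 / sqrt(f), 0)
  shaped_noise(n, ncols, amp)
}

#' Generate the ground-truth integrated/segregated regime timeline
#'
#' Alternating binary regimes (1 = integrated: the global source dominates;
#' 0 = segregated: community sources dominate) with dwell times drawn
#' uniformly within `epoch_s * (1 +/- jitter)`.  The starting regime is
#' drawn from the current RNG state.
#'
#' @param epoch_s Mean regime dwell time in seconds (> 0).
#' @param duration_s Total duration in seconds.
#' @param jitter Relative dwell jitter in `[0, 1)`; 0 gives exact tiling.
#' @return A data frame with columns `onset_s`, `offset_s`, `state`.
#' @export
generate_state_dynamics <- function(epoch_s, duration_s, jitter = 0.2) {
  stopifnot(epoch_s > 0, duration_s > 0)
  if (epoch_s > duration_s)
    warning("epoch_s exceeds duration_s: timeline has a single regime")
  state <- sample(0:1, 1L)
  onsets <- numeric(0); states <- integer(0); t0 <- 0
  while (t0 < duration_s) {
    dwell <- if (jitter > 0)
      epoch_s * stats::runif(1, 1 - jitter, 1 + jitter) else epoch_s
    onsets <- c(onsets, t0); states <- c(states, state)
    t0 <- t0 + dwell
    state <- 1L - state
  }
  data.frame(onset_s = onsets,
             offset_s = c(onsets[-1], duration_s),
             state = states)
}

# Expand a regime timeline to one value per sample.
timeline_samples <- function(timeline, n, rate) {
  idx <- findInterval((seq_len(n) - 1) / rate, timeline$onset_s)
  timeline$state[pmax(idx, 1L)]
}

#' Generate one band of coupled channel signals
#'
#' Each channel is `sqrt(g(t)) * shared + sqrt(w(t)) * community +
#' sqrt(u) * independent`, where every source is unit-variance
#' band-limited Gaussian noise (zero-phase order-4 Butterworth band-pass
#' of white noise), couplings g and w are variance fractions and
#' `u = 1 - g - w`.  With a regime timeline, the global coupling is
#' attenuated during segregated epochs and the community coupling during
#' integrated epochs.
#'
#' Uses the current RNG state; seed externally (e.g. with `set.seed()`)
#' for reproducibility.
#'
#' @param spec A [coupling_spec()].
#' @param duration_s Duration in seconds.
#' @param rate Sampling rate in Hz; must be at least twice the band's
#'   upper edge.
#' @param timeline Optional regime timeline from
#'   [generate_state_dynamics()].
#' @param regime_attenuation Gain multiplier applied to the non-dominant
#'   source during each regime (default 0.2).
#' @return A [band_signals()] object (16 channels).
#' @export
generate_band_sources <- function(spec, duration_s, rate, timeline = NULL,
                                  regime_attenuation = 0.2) {
  stopifnot(inherits(spec, "coupling_spec"))
  edges <- band_edges(spec$band)
  if (rate < 2 * edges[2])
    stop("rate must be >= 2x the band's upper edge (",
         2 * edges[2], " Hz)", call. = FALSE)
  n <- round(duration_s * rate)
  ch <- montage_channels()
  comm <- spec$community_assignment
  comm_levels <- unique(comm)

  shared <- band_noise(n, 1L, rate, edges)[, 1]
  comm_src <- band_noise(n, length(comm_levels), rate, edges)
  colnames(comm_src) <- comm_levels
  indep <- band_noise(n, length(ch), rate, edges)

  g <- spec$global_coupling
  w <- spec$within_community_coupling
  u <- sqrt(1 - g - w)
  if (is.null(timeline)) {
    g_t <- rep(sqrt(g), n); w_t <- rep(sqrt(w), n)
  } else {
    m <- timeline_samples(timeline, n, rate)
    a <- regime_attenuation
    g_t <- sqrt(g * (a + (1 - a) * m))  # full when integrated
    w_t <- sqrt(w * (1 - (1 - a) * m))  # full when segregated
  }
  data <- matrix(0, length(ch), n, dimnames = list(ch, NULL))
  for (i in seq_along(ch))
    data[i, ] <- g_t * shared + w_t * comm_src[, comm[ch[i]]] + u * indep[, i]
  band_signals(data, spec$band, rate, ch)
}

subject_seed <- function(seed, subject, cond_idx) {
  as.integer((as.numeric(seed) + 7919 * subject + 104729 * cond_idx) %%
               2147483647)
}

# Evaluate `code` under a fixed seed, restoring the caller RNG state.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate one subject-condition recording
#'
#' Sums the four planted band signals (scaled to `amplitude` microvolts RMS
#' each) and adds broadband pink noise; regime dynamics, when enabled, are
#' shared across bands within the recording.
#'
#' @param spec A [cohort_spec()].
#' @param subject Subject index in `1:n_subjects`.
#' @param condition Condition name present in `spec$conditions`.
#' @return An [eeg_recording()] with attribute `"ground_truth"` (list of
#'   planted gains and the regime timeline).
#' @export
generate_subject <- function(spec, subject, condition) {
  stopifnot(inherits(spec, "cohort_spec"),
            subject >= 1, subject <= spec$n_subjects)
  cond_idx <- match(condition, names(spec$conditions))
  if (is.na(cond_idx))
    stop("unknown condition '", condition, "'", call. = FALSE)
  bands <- spec$conditions[[condition]]
  with_local_seed(subject_seed(spec$seed, subject, cond_idx), {
    rate <- spec$sampling_rate
    n <- round(spec$duration_s * rate)
    timeline <- if (!is.null(spec$state_epoch_s))
      generate_state_dynamics(spec$state_epoch_s, spec$duration_s,
                              spec$dwell_jitter)
    m <- if (!is.null(timeline)) timeline_samples(timeline, n, rate)
    ch <- montage_channels()
    amp <- spec$amplitude
    acc <- matrix(0, n, 16L)            # samples x channels while mixing
    f <- (0:(n - 1)) * rate / n
    f <- pmin(f, rate - f)
    # coupled (shared + community) sources, per band
    gains <- list(); u_frac <- numeric(0)
    for (b in band_names()) {
      cs <- bands[[b]]
      comm <- cs$community_assignment
      lev <- unique(comm)
      src <- band_noise(n, 1L + length(lev), rate, band_edges(b))
      g <- cs$global_coupling; w <- cs$within_community_coupling
      if (is.null(m)) {
        g_t <- sqrt(g); w_t <- sqrt(w)
      } else {
        a <- 0.2                             # regime attenuation
        g_t <- sqrt(g * (a + (1 - a) * m))   # full when integrated
        w_t <- sqrt(w * (1 - (1 - a) * m))   # full when segregated
      }
      gs <- amp * (g_t * src[, 1])
      wc <- lapply(stats::setNames(seq_along(lev), lev), function(k)
        amp * (w_t * src[, 1 + k]))
      for (i in seq_along(ch))
        acc[, i] <- acc[, i] + gs + wc[[comm[ch[i]]]]
      gains[[b]] <- list(global = g, within = w)
      u_frac[b] <- 1 - g - w
    }
    # uncoupled background: the four bands' independent sources plus the
    # pink 1/f floor are independent Gaussians, so they are drawn as one
    # process per channel with the summed power spectrum
    noise_sd <- mean(vapply(bands, function(cs) cs$noise_sd, 0))
    pow <- numeric(n)
    for (b in band_names()) {
      h2 <- butter_bp_mag2(f, band_edges(b))
      pow <- pow + amp^2 * u_frac[b] * (h2 / shaped_noise_sd(n, h2))^2
    }
    if (noise_sd > 0) {
      pk <- numeric(n); pk[f > 0] <- 1 / sqrt(f[f > 0])
      pow <- pow + noise_sd^2 * (pk / shaped_noise_sd(n, pk))^2
    }
    total_sd <- sqrt(sum(amp^2 * u_frac) + noise_sd^2)
    if (total_sd > 0)
      acc <- acc + total_sd * shaped_noise(n, 16L, sqrt(pow))
    data <- t(acc)
    dimnames(data) <- list(ch, NULL)
    rec <- eeg_recording(data, rate = rate,
                         subject_id = sprintf("s%02d", subject),
                         condition = condition)
    attr(rec, "ground_truth") <- list(gains = gains, timeline = timeline,
                                      noise_sd = noise_sd)
    rec
  })
}

#' Generate a full synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `"eeg_cohort"`: `subjects` (per subject, a named
#'   list of [eeg_recording()] per condition) and `ledger` (planted
#'   parameters and regime timelines per recording).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  conds <- names(spec$conditions)
  subjects <- vector("list", spec$n_subjects)
  ledger <- list(spec_seed = spec$seed, recordings = list())
  for (s in seq_len(spec$n_subjects)) {
    recs <- lapply(stats::setNames(nm = conds), function(cond)
      generate_subject(spec, s, cond))
    subjects[[s]] <- recs
    for (cond in conds) {
      gt <- attr(recs[[cond]], "ground_truth")
      ledger$recordings[[sprintf("s%02d_%s", s, cond)]] <-
        list(subject = s, condition = cond, gains = gt$gains,
             noise_sd = gt$noise_sd,
             timeline = gt$timeline)
    }
  }
  structure(list(subjects = subjects, ledger = ledger, spec = spec),
            class = "eeg_cohort")
}

#' Write a cohort to disk
#'
#' One file per subject-condition recording plus a JSON ground-truth
#' ledger (`ledger.json`).
#'
#' @param cohort An `"eeg_cohort"` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (lossless, with JSON sidecars) or `"edf"`
#'   (16-bit quantized).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (recs in cohort$subjects)
    for (rec in recs) {
      stem <- file.path(dir, sprintf("%s_%s", rec$subject_id, rec$condition))
      if (format == "csv") write_eeg_csv(rec, paste0(stem, ".csv"))
      else write_edf(rec, paste0(stem, ".edf"))
    }
  jsonlite::write_json(cohort$ledger, file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
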