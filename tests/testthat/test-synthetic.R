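test_that("constant-HR configuration yields exactly periodic beats", {
  cfg <- simConfig(duration_s = 10, mean_hr_bpm = 60, hr_sd_bpm = 0,
                   rsa_amp_ms = 0, jitter_ms = 0)
  b <- simulateBeatTimes(cfg)
  expect_length(beatTimes(b), 10)
  expect_equal(beatTimes(b), 0:9, tolerance = 1e-12)
})

test_that("zero duration yields an empty annotation", {
  cfg <- simConfig(duration_s = 0)
  expect_length(beatTimes(simulateBeatTimes(cfg)), 0)
})

test_that("generated RR series recovers the configured mean heart rate", {
  cfg <- simConfig(duration_s = 60, mean_hr_bpm = 75, seed = 1)
  bt <- beatTimes(simulateBeatTimes(cfg))
  expect_lt(abs(mean(60 / diff(bt)) - 75), 3)
})

test_that("beat intervals always stay within the physiological range", {
  for (seed in 1:5) {
    cfg <- simConfig(duration_s = 30, hr_sd_bpm = 10, jitter_ms = 50,
                     seed = seed)
    rr <- diff(beatTimes(simulateBeatTimes(cfg)))
    expect_true(all(rr >= 60 / 180 - 1e-12 & rr <= 60 / 30 + 1e-12))
  }
})

test_that("invalid simulation configuration names the offending field", {
  expect_error(simConfig(mean_hr_bpm = 300), "mean_hr_bpm")
  expect_error(simConfig(fs = 10), "fs")
  expect_error(simConfig(dual_peak_prob = 1.5), "dual_peak_prob")
})

test_that("simulation is bitwise deterministic under a fixed seed", {
  cfg <- simConfig(duration_s = 20, seed = 42)
  b1 <- simulateBeatTimes(cfg); b2 <- simulateBeatTimes(cfg)
  expect_identical(beatTimes(b1), beatTimes(b2))
  r1 <- simulateScg(b1, cfg); r2 <- simulateScg(b2, cfg)
  expect_identical(scgSignal(r1), scgSignal(r2))
  m1 <- injectMotion(r1, artifactConfig(seed = 9))
  m2 <- injectMotion(r2, artifactConfig(seed = 9))
  expect_identical(scgSignal(m1$recording), scgSignal(m2$recording))
  expect_identical(m1$intervals, m2$intervals)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123); before <- .Random.seed
  simulateBeatTimes(simConfig(duration_s = 5, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("with no beats and no noise the signal is the respiration baseline", {
  cfg <- simConfig(duration_s = 10, noise_snr_db = Inf)
  rec <- simulateScg(beatAnnotation(numeric()), cfg)
  tgrid <- (0:(nSamples(rec) - 1)) / cfg$fs
  expected <- cfg$resp_amp * cfg$amplitude[1] *
    sin(2 * pi * cfg$resp_freq_hz * tgrid)
  expect_equal(scgSignal(rec)[, 1], expected, tolerance = 1e-12)
})

test_that("a single beat produces a wavelet peaking just after the beat", {
  cfg <- simConfig(duration_s = 10, noise_snr_db = Inf, resp_amp = 0,
                   am_depth = 0, dual_peak_prob = 0)
  rec <- simulateScg(beatAnnotation(5.0), cfg)
  for (ax in 1:3) {
    peak_t <- (which.max(abs(scgSignal(rec)[, ax])) - 1) / cfg$fs
    expect_lt(abs(peak_t - 5.0), cfg$decay_tau_s[ax] + 1e-9)
  }
})

test_that("beats outside the recording span are rejected", {
  cfg <- simConfig(duration_s = 10)
  expect_error(simulateScg(beatAnnotation(c(1, 10.5)), cfg), "duration")
})

test_that("empirical SNR matches the configured noise level within 1 dB", {
  cfg <- simConfig(duration_s = 60, noise_snr_db = 10, seed = 4)
  b <- simulateBeatTimes(cfg)
  noisy <- simulateScg(b, cfg)
  cfg_clean <- cfg; cfg_clean$noise_snr_db <- Inf
  clean <- simulateScg(b, cfg_clean)
  cfg_beat <- cfg_clean; cfg_beat$resp_amp <- 0
  beat_only <- simulateScg(b, cfg_beat)
  noise <- scgSignal(noisy) - scgSignal(clean)
  snr <- 10 * log10(mean(scgSignal(beat_only)^2) / mean(noise^2))
  expect_lt(abs(snr - 10), 1)
})

test_that("respiration power is concentrated below the 2 Hz high-pass cutoff", {
  cfg <- simConfig(duration_s = 60, noise_snr_db = Inf)
  rec <- simulateScg(beatAnnotation(numeric()), cfg)
  sp <- spec.pgram(ts(scgSignal(rec)[, 3], frequency = cfg$fs),
                   plot = FALSE, taper = 0)
  expect_gt(sum(sp$spec[sp$freq < 2]) / sum(sp$spec), 0.99)
})

test_that("zero burst rate leaves the recording untouched", {
  cfg <- simConfig(duration_s = 30)
  rec <- simulateScg(simulateBeatTimes(cfg), cfg)
  out <- injectMotion(rec, artifactConfig(burst_rate_per_min = 0))
  expect_identical(scgSignal(out$recording), scgSignal(rec))
  expect_equal(nrow(out$intervals), 0)
})

test_that("overlapping burst draws are merged into disjoint intervals", {
  cfg <- simConfig(duration_s = 120, seed = 5)
  rec <- simulateScg(simulateBeatTimes(cfg), cfg)
  found <- FALSE
  for (seed in 1:30) {
    out <- injectMotion(rec, artifactConfig(burst_rate_per_min = 4,
                                            burst_duration_s = 15,
                                            seed = seed))
    iv <- out$intervals
    if (nrow(iv) > 1L)
      expect_true(all(iv[-1, 1] > iv[-nrow(iv), 2]))
    if (nrow(iv) >= 1L) found <- TRUE
  }
  expect_true(found)
})

test_that("an injected high-energy burst is flagged exactly where placed", {
  cfg <- simConfig(duration_s = 300, seed = 8)
  rec <- simulateScg(simulateBeatTimes(cfg), cfg)
  out <- injectMotion(rec, artifactConfig(burst_rate_per_min = 0.4,
                                          energy_multiplier = 20, seed = 4))
  expect_gt(nrow(out$intervals), 0)
  fl <- flagArtifacts(segmentSpectralEnergy(out$recording))
  b <- fl$segment_bounds_s
  overlaps <- vapply(seq_len(nrow(b)), function(i)
    any(b[i, 1] < out$intervals[, 2] & b[i, 2] > out$intervals[, 1]),
    logical(1))
  expect_identical(fl$flags, overlaps)
})
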