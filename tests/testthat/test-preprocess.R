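test_that("upsampling a sinusoid tracks the analytic waveform within 1%", {
  t50 <- (0:499) / 50
  rec <- vecRecording(sin(2 * pi * t50), fs = 50)
  out <- resampleRecording(rec, 200)
  t200 <- (0:(nSamples(out) - 1)) / 200
  expect_lt(max(abs(scgSignal(out)[, 1] - sin(2 * pi * t200))), 0.01)
})

test_that("resampling to the native rate is the identity", {
  rec <- triRecording(rnorm(500), fs = 200)
  expect_identical(scgSignal(resampleRecording(rec, 200)), scgSignal(rec))
})

test_that("resampling preserves duration within one output sample", {
  rec <- vecRecording(rnorm(500), fs = 50)   # 10 s at 50 Hz
  out <- resampleRecording(rec, 200)
  expect_lte(abs(nSamples(out) - 4 * 500), 4)  # 4x count within one in-sample
  expect_lt(abs(duration(out) - duration(rec)), 1 / 200 + 1 / 50)
})

test_that("repeated resampling to the same rate is stable", {
  rec <- vecRecording(rnorm(1000), fs = 50)
  once <- resampleRecording(rec, 130)
  twice <- resampleRecording(once, 130)
  expect_equal(scgSignal(twice), scgSignal(once), tolerance = 1e-12)
})

test_that("a single-sample recording cannot be resampled", {
  expect_error(resampleRecording(vecRecording(1, fs = 50), 200), "single")
})

test_that("high-pass removes DC offset almost exactly", {
  rec <- vecRecording(rep(5, 2000), fs = 200)
  out <- scgSignal(highpassRecording(rec))[, 1]
  expect_lt(max(abs(out[300:1700])), 1e-6 * 5)
})

test_that("high-pass strongly attenuates sub-cutoff content", {
  t <- (0:(60 * 200 - 1)) / 200
  x <- sin(2 * pi * 0.3 * t)
  out <- scgSignal(highpassRecording(vecRecording(x, fs = 200)))[, 1]
  expect_lt(rms(out) / rms(x), 0.01)
})

test_that("high-pass passes in-band content within 1 dB", {
  t <- (0:(60 * 200 - 1)) / 200
  x <- sin(2 * pi * 15 * t)
  out <- scgSignal(highpassRecording(vecRecording(x, fs = 200)))[, 1]
  expect_gt(20 * log10(rms(out) / rms(x)), -1)
})

test_that("zero-phase filtering leaves a symmetric pulse peak in place", {
  x <- exp(-((0:1999) - 1000)^2 / (2 * 20^2))
  out <- scgSignal(highpassRecording(vecRecording(x, fs = 200)))[, 1]
  expect_equal(which.max(out), 1001)
})

test_that("high-pass is idempotent on in-band content away from edges", {
  t <- (0:(60 * 200 - 1)) / 200
  rec <- vecRecording(sin(2 * pi * 15 * t), fs = 200)
  once <- scgSignal(highpassRecording(rec))[, 1]
  twice <- scgSignal(highpassRecording(highpassRecording(rec)))[, 1]
  i <- 400:(length(once) - 400)        # steady-state region
  expect_lt(rms(twice[i] - once[i]) / rms(once[i]), 0.001)
})

test_that("recordings shorter than the filter warm-up are rejected", {
  expect_error(highpassRecording(vecRecording(rnorm(8), fs = 200)),
               "warm-up")
})

test_that("median scaling maps stable window bounds to [-1, 1]", {
  ch <- rep(c(-2, 2), length.out = 80)
  pp <- preprocessParams(scale_segment_len = 8)
  out <- scgSignal(medianScale(vecRecording(ch, fs = 200), pp))[, 1]
  expect_setequal(unique(out), c(-1, 1))
})

test_that("median scaling resists a single spiky window and clips it", {
  ch <- rep(c(-2, 2), length.out = 80)
  ch[37] <- 200                        # one 100x spike in window 5
  pp <- preprocessParams(scale_segment_len = 8)
  out <- scgSignal(medianScale(vecRecording(ch, fs = 200), pp))[, 1]
  # bounds still come from the normal windows: m = -2, M = 2
  expect_equal(sort(unique(out[-37])), c(-1, 1))
  expect_equal(out[37], 1.5)           # spike clipped
})

test_that("a flat channel maps to zero with a warning", {
  rec <- vecRecording(rep(3, 100), fs = 200)
  expect_warning(out <- medianScale(rec), "flat")
  expect_true(all(scgSignal(out) == 0))
})

test_that("median scaling is order-preserving up to clipping", {
  set.seed(3)
  x <- cumsum(rnorm(5000))
  pp <- preprocessParams(scale_segment_len = 512)
  y <- scgSignal(medianScale(vecRecording(x, fs = 200), pp))[, 1]
  inner <- y > -1.5 & y < 1.5
  expect_true(all(diff(y[inner])[diff(x[inner]) > 0] >= 0))
})

test_that("uniform timestamps form a single maximal run", {
  ts <- (0:999) / 200
  runs <- validateGaps(ts, 0.05)
  expect_equal(unname(runs), matrix(c(1L, 1001L), 1))
})

test_that("a single oversized gap splits the run in two", {
  ts <- c((0:499) / 200, 0.2 + (500:999) / 200)
  runs <- validateGaps(ts, 0.05)
  expect_equal(nrow(runs), 2)
  expect_equal(unname(runs[, 1]), c(1L, 501L))
  expect_equal(unname(runs[, 2]), c(501L, 1001L))
})

test_that("when every gap exceeds the limit each sample is its own run", {
  ts <- cumsum(rep(0.06, 50))
  runs <- validateGaps(ts, 0.05)
  expect_equal(nrow(runs), 50)
  expect_true(all(runs[, 2] - runs[, 1] == 1))
  # brute-force cross-check over random gap patterns
  set.seed(7)
  for (i in 1:20) {
    g <- runif(60, 0, 0.1)
    ts <- cumsum(g)
    runs <- validateGaps(ts, 0.05)
    covered <- unlist(lapply(seq_len(nrow(runs)),
                             function(r) runs[r, 1]:(runs[r, 2] - 1L)))
    expect_identical(sort(covered), 1:60)       # full disjoint cover
    # run starts exactly where the preceding gap exceeds the limit
    expect_identical(runs[, 1][-1], which(g[-1] > 0.05) + 1L)
  }
})

test_that("non-monotone timestamps are rejected", {
  expect_error(validateGaps(c(0, 0.1, 0.05), 0.05), "increasing")
})
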