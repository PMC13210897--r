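test_that("configuration guards reject inconsistent architectures", {
  expect_error(unetConfig(depth = 5, input_len = 1000), "divisible")
  expect_silent(unetConfig(depth = 5, input_len = 4096))
})

test_that("output probabilities are normalized per sample", {
  m <- buildUNet(unetConfig(depth = 2, init_filters = 4, kernel_size = 7,
                            input_len = 64), seed = 1)
  x <- array(rnorm(3 * 64 * 3), dim = c(3, 64, 3))
  p <- forwardUNet(m, x)
  expect_equal(dim(p), c(2, 64, 3))
  expect_true(all(abs(apply(p, c(2, 3), sum) - 1) < 1e-5))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("parameter count of a tiny network equals the hand-derived sum", {
  # depth 1, 2 initial filters, kernel 3, 3 input channels, 2 classes:
  # enc: conv 2x3x3+2=20, bn 4, conv 2x2x3+2=14, bn 4
  # bridge: conv 4x2x3+4=28, bn 8, conv 4x4x3+4=52, bn 8
  # up: 2x4x2+2=18; dec: conv 2x4x3+2=26, bn 4, conv 2x2x3+2=14, bn 4
  # head: 2x2x1+2=6  -> total 210
  m <- buildUNet(unetConfig(depth = 1, init_filters = 2, kernel_size = 3,
                            input_len = 8), seed = 1)
  expect_equal(unetParamCount(m), 210)
})

test_that("encoder filter counts double per stage from the initial width", {
  # parameter-count fingerprint: doubling init_filters roughly quadruples
  # conv weights at every stage, so the hand-computable formula below
  # must match the engine's count for several depths
  countFor <- function(depth, f0, k, cin = 3, classes = 2) {
    f <- f0 * 2^(0:(depth - 1))
    enc <- sum(f * c(cin, f[-depth]) * k + f + f * f * k + f + 4 * f)
    fb <- f0 * 2^depth
    bridge <- fb * f[depth] * k + fb + fb * fb * k + fb + 4 * fb
    dec <- sum(f * 2 * f * 2 + f +                 # transposed conv
               f * (2 * f) * k + f + f * f * k + f + 4 * f)
    head <- classes * f0 + classes
    enc + bridge + dec + head
  }
  for (d in 1:3) {
    m <- buildUNet(unetConfig(depth = d, init_filters = 4, kernel_size = 5,
                              input_len = 64), seed = 1)
    expect_equal(unetParamCount(m), countFor(d, 4, 5))
  }
})

test_that("network construction and training are seed-deterministic", {
  cfg <- unetConfig(depth = 2, init_filters = 4, kernel_size = 7,
                    input_len = 256)
  m1 <- buildUNet(cfg, seed = 5); m2 <- buildUNet(cfg, seed = 5)
  expect_identical(m1@state, m2@state)
  sb <- simulateSegmentBatch(6, simConfig(), input_len = 256, seed = 30)
  t1 <- trainUNet(m1, sb, sb, trainConfig(batch_size = 3, max_epochs = 2,
                                          seed = 9))
  t2 <- trainUNet(m2, sb, sb, trainConfig(batch_size = 3, max_epochs = 2,
                                          seed = 9))
  h1 <- attr(t1, "history"); h2 <- attr(t2, "history")
  expect_equal(h1$val_loss, h2$val_loss, tolerance = 1e-6)
  expect_identical(t1@state, t2@state)
})

test_that("the learning-rate schedule reacts to stalled validation loss", {
  # force a stall: validation targets are unrelated to the inputs
  set.seed(2)
  sb <- simulateSegmentBatch(4, simConfig(), input_len = 128, seed = 60)
  noise <- segmentBatch(array(rnorm(3 * 128 * 4), c(3, 128, 4)),
                        matrix(rbinom(128 * 4, 1, 0.5), 128, 4))
  m <- buildUNet(unetConfig(depth = 2, init_filters = 2, kernel_size = 5,
                            input_len = 128), seed = 1)
  tr <- trainUNet(m, sb, noise,
                  trainConfig(batch_size = 4, lr_init = 1e-3,
                              lr_patience_epochs = 2, lr_min = 1e-5,
                              max_epochs = 40, seed = 3))
  h <- attr(tr, "history")
  # whenever two consecutive epochs fail to improve the best loss, the
  # next epoch must run at a tenth of the rate (until the floor stops it)
  expect_true(any(h$lr < 1e-3))
  drops <- which(diff(h$lr) < 0)
  expect_true(all(h$lr[drops + 1] / h$lr[drops] - 0.1 < 1e-12))
  # schedule bottoms out at lr_min and then stops: no rate below the floor
  expect_true(all(h$lr >= 1e-5 - 1e-15))
  expect_lt(nrow(h), 40)               # early stop, not the epoch cap
})

test_that("a small network can overfit noiseless segments almost perfectly", {
  sb <- simulateSegmentBatch(50, simConfig(noise_snr_db = Inf,
                                           dual_peak_prob = 0),
                             input_len = 1024, seed = 11)
  m <- buildUNet(unetConfig(depth = 3, init_filters = 4, input_len = 1024),
                 seed = 3)
  tr <- trainUNet(m, sb, sb, trainConfig(batch_size = 8, max_epochs = 40,
                                         lr_patience_epochs = 4, seed = 5))
  p <- forwardUNet(tr, sb)
  acc <- mean((p[2, , ] > 0.5) == (sb$targets == 1))
  expect_gte(acc, 0.99)
})

test_that("whole-recording inference tiles windows with 50% overlap", {
  cfg <- unetConfig(depth = 2, init_filters = 4, kernel_size = 7,
                    input_len = 512)
  m <- buildUNet(cfg, seed = 4)
  set.seed(8)
  sig <- matrix(rnorm(768 * 3), ncol = 3)
  rec <- scgRecording(sig, fs = 200)
  out <- maskValues(predictProba(m, rec))
  expect_length(out, 768)
  # manual tiling: windows at offsets 0 and 256 (right-aligned tail)
  w1 <- forwardUNet(m, array(t(sig[1:512, ]), c(3, 512, 1)))[2, , 1]
  w2 <- forwardUNet(m, array(t(sig[257:768, ]), c(3, 512, 1)))[2, , 1]
  expect_equal(out[1:256], w1[1:256], tolerance = 1e-6)
  expect_equal(out[257:512], (w1[257:512] + w2[1:256]) / 2,
               tolerance = 1e-6)
  expect_equal(out[513:768], w2[257:512], tolerance = 1e-6)
  # a recording of exactly one window is a single un-averaged pass
  rec1 <- scgRecording(sig[1:512, ], fs = 200)
  expect_equal(maskValues(predictProba(m, rec1)), w1, tolerance = 1e-6)
})

test_that("models survive a save/load round trip", {
  cfg <- unetConfig(depth = 1, init_filters = 2, kernel_size = 3,
                    input_len = 32)
  m <- buildUNet(cfg, seed = 6)
  path <- tempfile(fileext = ".json")
  saveUNet(m, path)
  m2 <- loadUNet(path)
  x <- array(rnorm(3 * 32 * 2), c(3, 32, 2))
  expect_equal(forwardUNet(m, x), forwardUNet(m2, x), tolerance = 1e-6)
})

test_that("training rejects degenerate streams", {
  sb <- simulateSegmentBatch(2, simConfig(), input_len = 64, seed = 1)
  empty <- segmentBatch(array(0, c(3, 64, 0)), matrix(0L, 64, 0))
  m <- buildUNet(unetConfig(depth = 1, init_filters = 2, kernel_size = 3,
                            input_len = 64), seed = 1)
  expect_error(trainUNet(m, empty, sb), "empty")
  expect_error(trainUNet(m, sb, empty), "empty")
})
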