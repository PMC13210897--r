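test_that("matching follows the tolerance window", {
  m <- matchBeats(beatAnnotation(1.05), beatAnnotation(1.00), 0.1)
  expect_equal(unname(matchCounts(m)), c(1L, 0L, 0L))
  m <- matchBeats(beatAnnotation(1.15), beatAnnotation(1.00), 0.1)
  expect_equal(unname(matchCounts(m)), c(0L, 1L, 1L))
  # inclusive at exactly the tolerance
  m <- matchBeats(beatAnnotation(1.10), beatAnnotation(1.00), 0.1)
  expect_equal(unname(matchCounts(m))[1], 1L)
})

test_that("matching is one-to-one", {
  m <- matchBeats(beatAnnotation(c(1.0, 1.05)), beatAnnotation(1.0), 0.1)
  expect_equal(unname(matchCounts(m)), c(1L, 1L, 0L))
  expect_equal(nrow(matchPairs(m)), 1)
})

test_that("unsorted inputs are sorted with a warning", {
  expect_warning(m <- matchBeats(c(2.0, 1.0), beatAnnotation(c(1.0, 2.0))),
                 "unsorted")
  expect_equal(unname(matchCounts(m)), c(2L, 0L, 0L))
})

test_that("detection metrics follow their defining formulas", {
  mk <- function(tp, fp, fn) {
    pairs <- matrix(rep(seq_len(tp), 2), ncol = 2,
                    dimnames = list(NULL, c("pred", "ref")))
    new("MatchResult", pairs = pairs[seq_len(tp), , drop = FALSE],
        tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
        tolerance = 0.1)
  }
  expect_equal(detectionMetrics(mk(9, 1, 1)),
               c(ppv = 0.9, sensitivity = 0.9, f1 = 0.9))
  expect_equal(unname(detectionMetrics(mk(5, 0, 0))), c(1, 1, 1))
  m0 <- detectionMetrics(mk(0, 0, 3))
  expect_true(is.na(m0[["ppv"]]))
  expect_equal(m0[["sensitivity"]], 0)
})

test_that("greedy matching attains maximum cardinality for valid references", {
  set.seed(19)
  for (i in 1:500) {
    n_ref <- sample(3:10, 1)
    ref <- cumsum(runif(n_ref, 0.21, 1.0))    # spacing > 2 x tolerance
    keep <- runif(n_ref) < 0.8
    pred <- sort(c(ref[keep] + runif(sum(keep), -0.15, 0.15),
                   runif(sample(0:2, 1), 0, max(ref))))
    pred <- pred[c(TRUE, diff(pred) > 1e-6)]
    m <- matchBeats(beatAnnotation(pred), beatAnnotation(ref), 0.1)
    expect_equal(m@tp, bruteMaxMatch(pred, ref, 0.1))
  }
})

test_that("agreement statistics on identical and offset series", {
  h1 <- hrSeries(1:10 * 20, 60 + sin(1:10), rep(1, 10))
  a <- hrAgreement(h1, h1)
  expect_equal(a$mae_bpm, 0)
  expect_equal(a$rmse_bpm, 0)
  expect_equal(a$bias_bpm, 0)
  h2 <- hrSeries(1:10 * 20, hrValues(h1) + 2, rep(1, 10))
  a <- hrAgreement(h2, h1)
  expect_equal(a$mae_bpm, 2)
  expect_equal(a$rmse_bpm, 2)
  expect_equal(a$bias_bpm, 2)
  expect_equal(a$see_bpm, 0)
})

test_that("constant series have undefined correlation, not a forced value", {
  h1 <- hrSeries(1:5 * 20, rep(60, 5), rep(1, 5))
  expect_true(is.na(hrAgreement(h1, h1)$pearson_r))
})

test_that("agreement on random pairs matches the naive-formula oracle", {
  set.seed(23)
  for (i in 1:20) {
    n <- 100
    e <- rnorm(n, 70, 5); r <- e + rnorm(n, 0.5, 1)
    he <- hrSeries(1:n * 20, e, rep(1, n))
    hr <- hrSeries(1:n * 20, r, rep(1, n))
    a <- hrAgreement(he, hr)
    o <- bruteAgreement(e, r)
    expect_equal(a$mae_bpm, o$mae, tolerance = 1e-10)
    expect_equal(a$rmse_bpm, o$rmse, tolerance = 1e-10)
    expect_equal(a$pearson_r, o$r, tolerance = 1e-10)
    expect_equal(a$bias_bpm, o$bias, tolerance = 1e-10)
    expect_equal(c(a$loa_low_bpm, a$loa_high_bpm), o$loa, tolerance = 1e-10)
    expect_equal(a$see_bpm, o$see, tolerance = 1e-10)
  }
})

test_that("swapping series negates the bias and preserves error metrics", {
  set.seed(29)
  e <- rnorm(50, 70, 5); r <- e + rnorm(50, 1, 2)
  he <- hrSeries(1:50 * 20, e, rep(1, 50))
  hr <- hrSeries(1:50 * 20, r, rep(1, 50))
  a <- hrAgreement(he, hr); b <- hrAgreement(hr, he)
  expect_equal(a$bias_bpm, -b$bias_bpm)
  expect_equal(a$mae_bpm, b$mae_bpm)
  expect_equal(a$rmse_bpm, b$rmse_bpm)
  expect_equal(a$pearson_r, b$pearson_r)
})

test_that("windows without a defined HR on both sides are dropped", {
  he <- hrSeries(c(20, 40, 60), c(60, NA, 62), c(1, 0.3, 1))
  hr <- hrSeries(c(20, 40, 60, 80), c(61, 60, 61, 60), rep(1, 4))
  a <- hrAgreement(he, hr)
  expect_equal(a$n, 2)
  a2 <- hrAgreement(hrSeries(20, 60, 1), hrSeries(20, 60, 1))
  expect_true(is.na(a2$mae_bpm))      # < 2 common windows: undefined
})

test_that("F1 lies between PPV and sensitivity", {
  set.seed(31)
  for (i in 1:50) {
    tp <- sample(1:50, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    pairs <- matrix(rep(seq_len(tp), 2), ncol = 2,
                    dimnames = list(NULL, c("pred", "ref")))
    m <- new("MatchResult", pairs = pairs, tp = tp, fp = fp, fn = fn,
             tolerance = 0.1)
    dm <- detectionMetrics(m)
    expect_gte(dm[["f1"]], min(dm[["ppv"]], dm[["sensitivity"]]) - 1e-12)
    expect_lte(dm[["f1"]], max(dm[["ppv"]], dm[["sensitivity"]]) + 1e-12)
  }
})

test_that("beats inside flagged segments can be excluded from scoring", {
  beats <- beatAnnotation(seq(0.5, 29.5, by = 1))
  fl <- structure(list(segment_bounds_s = cbind(start_s = c(0, 10, 20),
                                                end_s = c(10, 20, 30)),
                       energies = c(1, 10, 1), flags = c(FALSE, TRUE, FALSE),
                       ratio_threshold = 5), class = "ArtifactFlags")
  kept <- beatTimes(excludeArtifactBeats(beats, fl))
  expect_true(all(kept < 10 | kept >= 20))
  expect_length(kept, 20)
})
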