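test_that("successive differences define the interval series", {
  ibi <- beatsToIbi(beatAnnotation(c(1, 2, 3)))
  expect_equal(ibiIntervals(ibi), c(1, 1))
  expect_equal(ibiOnsets(ibi), c(1, 2))
  expect_true(all(ibiFlags(ibi) == "good"))
  expect_length(beatsToIbi(beatAnnotation(5)), 0)
  expect_equal(ibiIntervals(beatsToIbi(beatAnnotation(c(0, 0.8, 1.55)))),
               c(0.8, 0.75))
})

test_that("a clean regular series passes through the corrector untouched", {
  ibi <- beatsToIbi(beatAnnotation(seq(0, 40, by = 0.8)))
  out <- correctIbi(ibi)
  expect_identical(ibiIntervals(out), ibiIntervals(ibi))
  expect_true(all(ibiFlags(out) == "good"))
})

test_that("a doubled interval is split as a missed beat, conserving span", {
  ibi <- ibiSeries(c(0, 0.8, 1.6, 3.2), c(0.8, 0.8, 1.6, 0.8))
  out <- correctIbi(ibi)
  expect_equal(ibiIntervals(out), c(0.8, 0.8, 0.8, 0.8, 0.8))
  expect_equal(ibiFlags(out), c("good", "good", "corrected", "corrected",
                                "good"))
  expect_equal(sum(ibiIntervals(out)), sum(ibiIntervals(ibi)))
})

test_that("a short pair is merged as an extra beat, conserving span", {
  ibi <- ibiSeries(c(0, 0.8, 1.2, 1.6), c(0.8, 0.4, 0.4, 0.8))
  out <- correctIbi(ibi)
  expect_equal(ibiIntervals(out), c(0.8, 0.8, 0.8))
  expect_equal(ibiFlags(out), c("good", "corrected", "good"))
  expect_equal(sum(ibiIntervals(out)), sum(ibiIntervals(ibi)))
})

test_that("a long/short adjacent pair is redistributed as a misaligned beat", {
  iv <- c(rep(0.8, 6), 1.1, 0.5, rep(0.8, 6))
  ibi <- ibiSeries(cumsum(c(0, iv[-length(iv)])), iv)
  out <- correctIbi(ibi)
  expect_equal(sum(ibiIntervals(out)), sum(iv))
  expect_equal(ibiIntervals(out)[7:8], c(0.8, 0.8))
  expect_equal(ibiFlags(out)[7:8], c("corrected", "corrected"))
})

test_that("corrections conserve the spanned time on random corruptions", {
  set.seed(9)
  for (i in 1:20) {
    rr <- 0.75 + 0.05 * sin(seq(0, 8, length.out = 60)) + rnorm(60, 0, 0.01)
    # corrupt: delete a beat (merge two intervals) and add an extra beat
    del <- sample(5:50, 1)
    rr2 <- c(rr[1:(del - 1)], rr[del] + rr[del + 1], rr[(del + 2):60])
    add <- sample(5:50, 1)
    rr3 <- c(rr2[1:(add - 1)], rr2[add] * 0.45, rr2[add] * 0.55,
             rr2[(add + 1):length(rr2)])
    ibi <- ibiSeries(cumsum(c(0.5, rr3[-length(rr3)])), rr3)
    out <- correctIbi(ibi)
    n_corr <- sum(ibiFlags(out) == "corrected")
    expect_lt(abs(sum(ibiIntervals(out)) - sum(rr3)),
              1e-3 * max(n_corr, 1))
  }
})

test_that("heart rate follows the 60 / mean(IBI) identity", {
  ibi <- ibiSeries(cumsum(c(0, rep(1, 20))), rep(1, 21))
  hr <- estimateHr(ibi, window_s = 20)
  expect_true(all(hrValues(hr) == 60))
  # fraction 0.6 window with mean 0.75 s intervals -> 80 bpm
  iv <- rep(0.75, 16)                            # 12 s of good data
  fill <- rep(0.8, 11)                           # excluded remainder
  ibi <- ibiSeries(cumsum(c(0, c(iv, fill)[-27])), c(iv, fill),
                   c(rep("good", 16), rep("excluded", 11)))
  hr <- estimateHr(ibi, window_s = 20, t_origin = 0)
  expect_equal(effectiveFraction(hr)[1], 0.6)
  expect_equal(hrValues(hr)[1], 80)
})

test_that("the effective-length gate is strict at one half", {
  gateCase <- function(good_iv) {
    n <- length(good_iv)
    fill <- rep(0.8, 15)
    iv <- c(good_iv, fill)
    ibi <- ibiSeries(cumsum(c(0, iv[-length(iv)])), iv,
                     c(rep("good", n), rep("excluded", 15)))
    estimateHr(ibi, window_s = 20, t_origin = 0)
  }
  hr <- gateCase(rep(0.9, 11))                   # 9.9 s: fraction 0.495
  expect_equal(effectiveFraction(hr)[1], 0.495)
  expect_true(is.na(hrValues(hr)[1]))
  hr <- gateCase(rep(1.01, 10))                  # 10.1 s: fraction 0.505
  expect_equal(effectiveFraction(hr)[1], 0.505)
  expect_equal(hrValues(hr)[1], 60 / 1.01)
})

test_that("relaxing the gate never reduces the number of defined windows", {
  set.seed(13)
  iv <- runif(120, 0.6, 1.0)
  fl <- sample(c("good", "excluded"), 120, TRUE, prob = c(0.6, 0.4))
  ibi <- ibiSeries(cumsum(c(0, iv[-120])), iv, fl)
  counts <- vapply(c(0.7, 0.5, 0.3, 0.1), function(g)
    sum(!is.na(hrValues(estimateHr(ibi, 20, 10, min_effective = g)))),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("defined heart rates stay within physiological bounds", {
  set.seed(14)
  for (i in 1:10) {
    iv <- runif(80, 60 / 180, 60 / 30)
    ibi <- ibiSeries(cumsum(c(0, iv[-80])), iv)
    hr <- hrValues(estimateHr(ibi, 20, 10))
    expect_true(all(is.na(hr) | (hr > 20 & hr < 240)))
  }
})

test_that("correction recovers windowed HR after random beat deletions", {
  set.seed(15)
  h <- 70
  beats <- seq(0, 120, by = 60 / h)
  del <- sample(seq(5, length(beats) - 5), round(0.1 * length(beats)))
  corrupted <- beatAnnotation(beats[-del])
  out <- correctIbi(beatsToIbi(corrupted))
  hr <- hrValues(estimateHr(out, window_s = 20))
  expect_true(all(!is.na(hr)))
  expect_lt(mean(abs(hr - h)), 0.5)
})

test_that("intervals overlapping artifact segments are excluded", {
  ibi <- beatsToIbi(beatAnnotation(seq(0, 40, by = 0.8)))
  out <- excludeArtifactIbi(ibi, matrix(c(10, 15), 1))
  on <- ibiOnsets(out); en <- on + ibiIntervals(out)
  hit <- on < 15 & en > 10
  expect_true(all(ibiFlags(out)[hit] == "excluded"))
  expect_true(all(ibiFlags(out)[!hit] == "good"))
})
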