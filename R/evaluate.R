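#' Tolerance-based one-to-one beat matching
#'
#' Chronological greedy matching: predictions are scanned in time order
#' and each is paired with the nearest not-yet-matched reference beat
#' within `tolerance_s` (tie: the earlier reference). Matched pairs are
#' true positives; unmatched references are false negatives; unmatched
#' predictions are false positives. For physiologically valid references
#' (spacing greater than twice the tolerance) the greedy pairing attains
#' the maximum possible number of matches.
#'
#' @param pred,ref [BeatAnnotation-class] objects (unsorted numeric input
#'   is sorted with a warning).
#' @param tolerance_s matching tolerance in seconds, inclusive
#'   (default 0.1).
#' @return a [MatchResult-class].
#' @examples
#' m <- matchBeats(beatAnnotation(c(1.05, 2.0)), beatAnnotation(c(1.0, 2.5)))
#' matchCounts(m)
#' @export
matchBeats <- function(pred, ref, tolerance_s = 0.1) {
  asBeats <- function(x, what) {
    if (is(x, "BeatAnnotation")) return(beatTimes(x))
    x <- as.numeric(x)
    if (is.unsorted(x, strictly = TRUE)) {
      warning(sprintf("unsorted %s beats: sorting", what), call. = FALSE)
      x <- sort(x)
    }
    x
  }
  p <- asBeats(pred, "predicted")
  r <- asBeats(ref, "reference")
  used <- rep(FALSE, length(r))
  pairs <- matrix(numeric(), 0, 2, dimnames = list(NULL, c("pred", "ref")))
  for (i in seq_along(p)) {
    if (!length(r)) break
    d <- abs(r - p[i])
    d[used] <- Inf
    j <- which.min(d)            # ties resolve to the earlier reference
    if (is.finite(d[j]) && d[j] <= tolerance_s + 1e-12) {
      used[j] <- TRUE
      pairs <- rbind(pairs, c(p[i], r[j]))
    }
  }
  new("MatchResult", pairs = pairs, tp = nrow(pairs),
      fp = length(p) - nrow(pairs), fn = sum(!used),
      tolerance = tolerance_s)
}

#' Detection metrics from a match result
#'
#' @param m a [MatchResult-class].
#' @return named numeric vector with `ppv` = TP/(TP+FP), `sensitivity` =
#'   TP/(TP+FN) and `f1` (harmonic mean); a metric with a zero
#'   denominator is `NA` (undefined), never coerced to 0.
#' @export
detectionMetrics <- function(m) {
  stopifnot(is(m, "MatchResult"))
  tp <- m@tp; fp <- m@fp; fn <- m@fn
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0)
    2 * ppv * sens / (ppv + sens) else NA_real_
  c(ppv = ppv, sensitivity = sens, f1 = f1)
}

#' Agreement statistics between estimated and reference heart rate
#'
#' Pairs the two series on their common defined windows (matching window
#' centres, both HR values defined) and computes mean absolute error,
#' root-mean-square error, Pearson correlation, and the Bland-Altman
#' summary: bias = mean(est - ref), limits of agreement = bias +/- 1.96
#' SD of the differences, and SEE = that SD. Pearson correlation on a
#' zero-variance input is reported as `NA` (undefined).
#'
#' @param est,ref [HrSeries-class] objects on the same timeline.
#' @param center_tol tolerance in seconds when matching window centres.
#' @return list of class `AgreementStats` with elements `mae_bpm`,
#'   `rmse_bpm`, `pearson_r`, `bias_bpm`, `loa_low_bpm`, `loa_high_bpm`,
#'   `see_bpm`, `n`. With fewer than 2 common windows all statistics are
#'   `NA`.
#' @export
hrAgreement <- function(est, ref, center_tol = 1e-6) {
  stopifnot(is(est, "HrSeries"), is(ref, "HrSeries"))
  ec <- windowCenters(est); rc <- windowCenters(ref)
  idx <- outer(ec, rc, function(a, b) abs(a - b) <= center_tol)
  common <- which(idx, arr.ind = TRUE)
  e <- hrValues(est)[common[, 1]]
  r <- hrValues(ref)[common[, 2]]
  ok <- !is.na(e) & !is.na(r)
  e <- e[ok]; r <- r[ok]
  n <- length(e)
  if (n < 2L) {
    res <- list(mae_bpm = NA_real_, rmse_bpm = NA_real_,
                pearson_r = NA_real_, bias_bpm = NA_real_,
                loa_low_bpm = NA_real_, loa_high_bpm = NA_real_,
                see_bpm = NA_real_, n = n)
    class(res) <- "AgreementStats"
    return(res)
  }
  d <- e - r
  bias <- mean(d)
  s <- sd(d)
  pr <- if (sd(e) > 0 && sd(r) > 0) cor(e, r) else NA_real_
  res <- list(mae_bpm = mean(abs(d)),
              rmse_bpm = sqrt(mean(d^2)),
              pearson_r = pr,
              bias_bpm = bias,
              loa_low_bpm = bias - 1.96 * s,
              loa_high_bpm = bias + 1.96 * s,
              see_bpm = s,
              n = n)
  class(res) <- "AgreementStats"
  res
}

#' @export
print.AgreementStats <- function(x, ...) {
  cat(sprintf(paste0("HR agreement on %d windows: MAE %.3f bpm, RMSE %.3f bpm,",
                     " r %.4f\n  bias %.3f bpm, LoA [%.3f, %.3f] bpm, SEE %.3f bpm\n"),
              x$n, x$mae_bpm, x$rmse_bpm, x$pearson_r, x$bias_bpm,
              x$loa_low_bpm, x$loa_high_bpm, x$see_bpm))
  invisible(x)
}

#' Drop beats that fall inside flagged artifact segments
#'
#' Evaluation helper mirroring the artifact-exclusion protocol: removes
#' from an annotation every beat lying within a flagged segment.
#'
#' @param beats a [BeatAnnotation-class].
#' @param flags an `ArtifactFlags` object or two-column matrix of
#'   flagged `(start_s, end_s)` intervals.
#' @return the filtered [BeatAnnotation-class].
#' @export
excludeArtifactBeats <- function(beats, flags) {
  stopifnot(is(beats, "BeatAnnotation"))
  seg <- if (inherits(flags, "ArtifactFlags"))
    flags$segment_bounds_s[flags$flags, , drop = FALSE]
  else as.matrix(flags)
  bt <- beatTimes(beats)
  if (!nrow(seg) || !length(bt)) return(beats)
  inside <- vapply(bt, function(b) any(b >= seg[, 1] & b < seg[, 2]),
                   logical(1))
  beatAnnotation(bt[!inside])
}
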