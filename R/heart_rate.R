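#' Successive inter-beat intervals from beat times
#'
#' @param beats a [BeatAnnotation-class].
#' @return an [IbiSeries-class] with one interval per successive beat
#'   pair, onset at the earlier beat, all flags `good`; empty when fewer
#'   than two beats.
#' @export
beatsToIbi <- function(beats) {
  stopifnot(is(beats, "BeatAnnotation"))
  bt <- beatTimes(beats)
  if (length(bt) < 2L) return(ibiSeries(numeric(), numeric()))
  ibiSeries(onsets = bt[-length(bt)], intervals = diff(bt))
}

#' Correct implausible inter-beat intervals
#'
#' Running-median/quartile-deviation corrector for missed, extra and
#' misaligned beats. Each interval is compared with its running median
#' (window `med_window`); the decision threshold is
#' `min(max(alpha * QD, th_min), rel_max * median)`, where QD is the
#' quartile deviation (IQR/2) of the deviations from the running median.
#' Flagged intervals are reconciled as:
#' \itemize{
#'   \item near an integer multiple `k >= 2` of the local median:
#'     a run of `k - 1` missed beats; the interval is split into `k`
#'     equal parts (`corrected`);
#'   \item a long/short adjacent pair whose mean is plausible:
#'     a misaligned beat; both intervals are set to their mean
#'     (`corrected`);
#'   \item a short adjacent pair whose sum is plausible: an extra beat;
#'     the pair is merged (`corrected`);
#'   \item anything else: `excluded`.
#' }
#' Every correction conserves the total spanned time exactly. This is a
#' deliberately simple, fully documented quality stand-in; it does not
#' reproduce any proprietary beat-classification software.
#'
#' @param ibi an [IbiSeries-class].
#' @param med_window running-median window in beats (odd, default 11).
#' @param alpha multiplier on the quartile deviation (default 3).
#' @param th_min floor of the threshold in seconds (default 0.03).
#' @param rel_max ceiling of the threshold as a fraction of the local
#'   median (default 0.3).
#' @return the corrected [IbiSeries-class].
#' @export
correctIbi <- function(ibi, med_window = 11, alpha = 3, th_min = 0.03,
                       rel_max = 0.3) {
  stopifnot(is(ibi, "IbiSeries"))
  if (length(ibi) == 0L) return(ibi)
  iv <- ibiIntervals(ibi)
  fl <- ibiFlags(ibi)
  # Corrections run in phases (extra-beat merges, missed-beat splits,
  # misaligned-pair redistribution, exclusion), re-estimating the running
  # median and thresholds after each phase so that a repaired stretch no
  # longer biases the statistics for the next decision.
  stats <- function(iv) {
    n <- length(iv)
    half <- floor(med_window / 2)
    locmed <- vapply(seq_len(n), function(i)
      median(iv[max(1, i - half):min(n, i + half)]), numeric(1))
    dev <- iv - locmed
    qd <- diff(quantile(dev, c(0.25, 0.75), names = FALSE)) / 2
    th <- pmin(pmax(alpha * qd, th_min), rel_max * locmed)
    # plausibility of a repaired interval is judged more leniently than
    # the flagging threshold: the local median itself is biased on short
    # corrupted stretches
    list(locmed = locmed, dev = dev, th = th,
         tolr = pmax(th, 0.35 * locmed))
  }

  # phase 1: extra beats -- adjacent short pairs whose sum is plausible
  s <- stats(iv)
  out_iv <- list(); out_fl <- list(); i <- 1L
  while (i <= length(iv)) {
    if (i < length(iv) && s$dev[i] < -s$th[i] &&
        s$dev[i + 1L] < -s$th[i + 1L] &&
        abs(iv[i] + iv[i + 1L] - s$locmed[i]) <= s$tolr[i]) {
      out_iv[[length(out_iv) + 1L]] <- iv[i] + iv[i + 1L]
      out_fl[[length(out_fl) + 1L]] <- "corrected"
      i <- i + 2L
    } else {
      out_iv[[length(out_iv) + 1L]] <- iv[i]
      out_fl[[length(out_fl) + 1L]] <- fl[i]
      i <- i + 1L
    }
  }
  iv <- unlist(out_iv); fl <- unlist(out_fl)

  # phase 2: missed beats -- intervals near an integer multiple of the
  # local median are split into equal plausible parts
  s <- stats(iv)
  out_iv <- list(); out_fl <- list()
  for (i in seq_along(iv)) {
    k <- round(iv[i] / s$locmed[i])
    if (s$dev[i] > s$th[i] && k >= 2 &&
        abs(iv[i] / k - s$locmed[i]) <= s$tolr[i]) {
      out_iv[[length(out_iv) + 1L]] <- rep(iv[i] / k, k)
      out_fl[[length(out_fl) + 1L]] <- rep("corrected", k)
    } else {
      out_iv[[length(out_iv) + 1L]] <- iv[i]
      out_fl[[length(out_fl) + 1L]] <- fl[i]
    }
  }
  iv <- unlist(out_iv); fl <- unlist(out_fl)

  # phase 3: misaligned beats -- long/short adjacent pairs with a
  # plausible mean are redistributed; span conserved exactly
  s <- stats(iv)
  out_iv <- list(); out_fl <- list(); i <- 1L
  while (i <= length(iv)) {
    if (i < length(iv) && abs(s$dev[i]) > s$th[i] &&
        abs(s$dev[i + 1L]) > s$th[i + 1L] &&
        sign(s$dev[i]) != sign(s$dev[i + 1L]) &&
        abs((iv[i] + iv[i + 1L]) / 2 - s$locmed[i]) <= s$tolr[i]) {
      out_iv[[length(out_iv) + 1L]] <- rep((iv[i] + iv[i + 1L]) / 2, 2)
      out_fl[[length(out_fl) + 1L]] <- rep("corrected", 2)
      i <- i + 2L
    } else {
      out_iv[[length(out_iv) + 1L]] <- iv[i]
      out_fl[[length(out_fl) + 1L]] <- fl[i]
      i <- i + 1L
    }
  }
  iv <- unlist(out_iv); fl <- unlist(out_fl)

  # phase 4: whatever still deviates and could not be reconciled
  s <- stats(iv)
  fl[abs(s$dev) > s$th & fl == "good"] <- "excluded"

  onset0 <- ibiOnsets(ibi)[1]
  ibiSeries(onset0 + c(0, cumsum(iv)[-length(iv)]), iv, fl)
}

#' Exclude intervals overlapping flagged artifact segments
#'
#' Marks as `excluded` every interval that overlaps a motion-artifact
#' segment, the quality role otherwise played by a dedicated
#' signal-quality classifier.
#'
#' @param ibi an [IbiSeries-class].
#' @param flags an `ArtifactFlags` object from [flagArtifacts()], or a
#'   two-column matrix of flagged `(start_s, end_s)` intervals.
#' @return the [IbiSeries-class] with overlapping intervals excluded.
#' @export
excludeArtifactIbi <- function(ibi, flags) {
  stopifnot(is(ibi, "IbiSeries"))
  seg <- if (inherits(flags, "ArtifactFlags"))
    flags$segment_bounds_s[flags$flags, , drop = FALSE]
  else as.matrix(flags)
  if (!nrow(seg)) return(ibi)
  on <- ibiOnsets(ibi); en <- on + ibiIntervals(ibi)
  fl <- ibiFlags(ibi)
  hit <- vapply(seq_along(on), function(i)
    any(on[i] < seg[, 2] & en[i] > seg[, 1]), logical(1))
  fl[hit] <- "excluded"
  ibiSeries(on, ibiIntervals(ibi), fl)
}

#' Windowed heart-rate estimation with an effective-length gate
#'
#' Slides a fixed window over the interval series; within each window the
#' effective length is the summed duration of `good` intervals lying
#' fully inside the window, divided by the window length. When the
#' effective fraction strictly exceeds `min_effective`, the heart rate is
#' `60 / mean(IBI)` over those good intervals; otherwise the window's HR
#' is undefined (`NA`).
#'
#' @param ibi an [IbiSeries-class].
#' @param window_s window length in seconds (default 20).
#' @param step_s window step in seconds (default `window_s`,
#'   non-overlapping).
#' @param min_effective gate on the effective fraction, strict
#'   comparison (default 0.5).
#' @param t_origin start of the window grid in seconds; `NULL` (default)
#'   anchors it at the first interval onset. Supplying a fixed origin
#'   puts independently detected series on a common grid so their
#'   windows can be paired for agreement analysis.
#' @return an [HrSeries-class] with one entry per window.
#' @export
estimateHr <- function(ibi, window_s = 20, step_s = window_s,
                       min_effective = 0.5, t_origin = NULL) {
  stopifnot(is(ibi, "IbiSeries"))
  window_s <- stopIfNot1(window_s, "window_s", 1e-9)
  step_s <- stopIfNot1(step_s, "step_s", 1e-9)
  n <- length(ibi)
  if (n == 0L) return(hrSeries(numeric(), numeric(), numeric()))
  on <- ibiOnsets(ibi); iv <- ibiIntervals(ibi); fl <- ibiFlags(ibi)
  t_start <- if (is.null(t_origin)) on[1] else as.numeric(t_origin)
  t_end <- on[n] + iv[n]
  if (t_end - t_start < window_s)
    return(hrSeries(numeric(), numeric(), numeric()))
  centers <- seq(t_start + window_s / 2, t_end - window_s / 2 + 1e-12,
                 by = step_s)
  hr <- ef <- numeric(length(centers))
  for (w in seq_along(centers)) {
    lo <- centers[w] - window_s / 2; hi <- centers[w] + window_s / 2
    inside <- on >= lo - 1e-9 & (on + iv) <= hi + 1e-9
    good <- inside & fl == "good"
    ef[w] <- sum(iv[good]) / window_s
    hr[w] <- if (ef[w] > min_effective) 60 / mean(iv[good]) else NA_real_
  }
  hrSeries(centers, hr, pmin(ef, 1))
}
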