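#' Convert RR intervals to absolute beat times
#'
#' Beat `k` lies at `anchorS` plus the cumulative sum of the first `k`
#' intervals, converted to seconds, i.e. the reference beat events
#' implied by a beat-to-beat RR stream anchored on the recording
#' timeline.
#'
#' @param rr an [RrSeries-class].
#' @return a [BeatAnnotation-class]; empty when the series is empty.
#' @examples
#' rrToBeatTimes(rrSeries(c(800, 750), anchorS = 0.5))
#' @export
rrToBeatTimes <- function(rr) {
  stopifnot(is(rr, "RrSeries"))
  if (!length(rr@intervalsMs)) return(beatAnnotation(numeric()))
  beatAnnotation(rr@anchorS + cumsum(rr@intervalsMs) / 1000)
}

#' Estimate the RR-stream anchor by envelope correlation
#'
#' The temporal offset between an external RR stream and the SCG sample
#' clock is generally unknown. This helper scans candidate anchors and
#' returns the one whose implied beat windows capture the most
#' beat-band signal energy (smoothed envelope of the preprocessed
#' recording). It is an optional aid: every function in the package
#' takes the anchor as an explicit parameter and never guesses it.
#'
#' @param rec a preprocessed (high-passed) [ScgRecording-class].
#' @param rr an [RrSeries-class]; its own `anchorS` is ignored.
#' @param search_s length-2 range of candidate anchors in seconds.
#' @param step_s grid step in seconds (default 0.01).
#' @param half_width_s beat-window half-width used for scoring.
#' @return the best anchor in seconds (a scalar). The estimate aligns
#'   beats to the wavelet energy peak, which trails beat onset by a few
#'   tens of milliseconds -- ample for the 0.1 s mask half-width, but
#'   not a fiducial-grade alignment.
#' @export
estimateRrAnchor <- function(rec, rr, search_s = c(0, 2), step_s = 0.01,
                             half_width_s = 0.1) {
  stopifnot(is(rec, "ScgRecording"), is(rr, "RrSeries"))
  fs <- samplingRate(rec)
  env <- rowSums(abs(scgSignal(rec)))
  k <- max(1L, round(half_width_s * fs))
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  offsets_s <- cumsum(rr@intervalsMs) / 1000
  n <- nSamples(rec)
  cand <- seq(search_s[1], search_s[2], by = step_s)
  scores <- vapply(cand, function(a) {
    idx <- round((a + offsets_s) * fs) + 1L
    idx <- idx[idx >= 1L & idx <= n]
    if (!length(idx)) return(-Inf)
    mean(env[idx])
  }, numeric(1))
  cand[which.max(scores)]
}

#' Rasterize beat times into a per-sample binary mask
#'
#' Marks every sample within `half_width_s` of a beat time as 1 (the
#' symmetric 0.1 s half-width yields a 0.2 s reference window per beat),
#' 0 elsewhere. Windows of nearby beats merge by logical OR; windows are
#' truncated at the mask edges.
#'
#' @param beats a [BeatAnnotation-class]; all beat times must fall within
#'   the mask's time span.
#' @param fs sampling rate of the mask in Hz.
#' @param length number of samples in the mask.
#' @param half_width_s half-width of the symmetric window in seconds
#'   (default 0.1).
#' @param t0 time of the first mask sample in seconds.
#' @return a binary [SampleMask-class] of `length` samples.
#' @examples
#' m <- beatsToMask(beatAnnotation(2.0), fs = 200, length = 1000)
#' sum(maskValues(m))  # 41 samples: +/- 0.1 s at 200 Hz
#' @export
beatsToMask <- function(beats, fs, length, half_width_s = 0.1, t0 = 0) {
  stopifnot(is(beats, "BeatAnnotation"))
  fs <- stopIfNot1(fs, "fs", 1e-9)
  length <- as.integer(stopIfNot1(length, "length", 1))
  bt <- beatTimes(beats)
  t_end <- t0 + (length - 1L) / fs
  if (base::length(bt) && (any(bt < t0) || any(bt > t_end + 1 / fs)))
    stop("beat time beyond the mask duration")
  v <- numeric(length)
  hw <- half_width_s * fs
  for (b in bt) {
    c_idx <- (b - t0) * fs             # 0-based fractional sample index
    lo <- max(ceiling(c_idx - hw - 1e-9), 0)
    hi <- min(floor(c_idx + hw + 1e-9), length - 1L)
    if (hi >= lo) v[(lo:hi) + 1L] <- 1
  }
  sampleMask(v, fs = fs, t0 = t0)
}
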