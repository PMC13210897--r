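#' Beat-localization parameters
#'
#' Rule set that turns a per-sample heartbeat-probability mask into
#' discrete beat times: interpolation rate, confidence threshold,
#' minimum mask width (80% of the 0.2 s reference window at 1000 Hz),
#' and the physiological minimum separation between beats.
#'
#' @param interp_fs interpolation rate in Hz (default 1000).
#' @param prob_threshold confidence threshold in (0, 1), strict
#'   comparison (default 0.8).
#' @param min_width_samples minimum run width in samples at `interp_fs`
#'   (default 160).
#' @param min_separation_s minimum separation between consecutive beats
#'   in seconds (default 0.55).
#' @return a validated list of class `DetectionParams`.
#' @export
detectionParams <- function(interp_fs = 1000, prob_threshold = 0.8,
                            min_width_samples = 160,
                            min_separation_s = 0.55) {
  p <- list(interp_fs = stopIfNot1(interp_fs, "interp_fs", 1e-9),
            prob_threshold = stopIfNot1(prob_threshold, "prob_threshold",
                                        1e-12, 1 - 1e-12),
            min_width_samples = stopIfNot1(min_width_samples,
                                           "min_width_samples", 1),
            min_separation_s = stopIfNot1(min_separation_s,
                                          "min_separation_s", 1e-12))
  class(p) <- "DetectionParams"
  p
}

#' Localize heartbeats in a probability mask
#'
#' Applies the rule-based localization pipeline: (1) linear
#' interpolation of the mask to `interp_fs`; (2) binarization at
#' `prob_threshold` (strictly greater); (3) extraction of maximal
#' supra-threshold runs; (4) removal of runs narrower than
#' `min_width_samples`; (5) enforcement of `min_separation_s` between
#' consecutive surviving runs -- when two runs conflict, the run with the
#' higher mean probability survives (tie: the earlier run), re-checking
#' left to right; (6) the beat time is the mean sample index of each
#' surviving run on the recording timeline.
#'
#' @param prob a [SampleMask-class] of probabilities.
#' @param params a [detectionParams()] object.
#' @return a [BeatAnnotation-class] (empty when no run survives).
#' @export
localizeBeats <- function(prob, params = detectionParams()) {
  stopifnot(is(prob, "SampleMask"))
  v <- maskValues(prob)
  fs <- samplingRate(prob)
  n <- length(v)
  if (n < 2L || max(v) <= params$prob_threshold)
    return(beatAnnotation(numeric()))
  # (1) interpolate onto the interp_fs grid spanning the same time range
  m <- floor((n - 1L) / fs * params$interp_fs) + 1L
  idx_new <- (seq_len(m) - 1L) / params$interp_fs      # seconds from t0
  p <- approx((seq_len(n) - 1L) / fs, v, xout = idx_new)$y
  # (2)-(3) supra-threshold runs
  above <- p > params$prob_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  # (4) width filter
  wide <- (ends - starts + 1L) >= params$min_width_samples
  starts <- starts[wide]; ends <- ends[wide]
  if (!length(starts)) return(beatAnnotation(numeric()))
  centers <- (starts + ends) / 2 - 1                   # mean 0-based index
  times <- timeOrigin(prob) + centers / params$interp_fs
  score <- vapply(seq_along(starts),
                  function(i) mean(p[starts[i]:ends[i]]), numeric(1))
  # (5) separation rule, left-to-right re-check
  i <- 1L
  while (i < length(times)) {
    if (times[i + 1L] - times[i] < params$min_separation_s) {
      drop <- if (score[i + 1L] > score[i]) i else i + 1L
      times <- times[-drop]; score <- score[-drop]
      i <- max(i - 1L, 1L)
    } else i <- i + 1L
  }
  beatAnnotation(times)
}
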