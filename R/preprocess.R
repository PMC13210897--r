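#' Preprocessing parameters
#'
#' Bundles the signal-conditioning settings applied before segmentation:
#' resampling target, zero-phase high-pass design, median-based scaling
#' window, and the maximum tolerated inter-sample gap for wrist-worn
#' (non-uniformly delivered) data.
#'
#' @param target_fs uniform sampling rate after resampling, Hz
#'   (default 200).
#' @param hp_cutoff_hz high-pass cutoff, Hz (default 2).
#' @param hp_order high-pass filter order, even and >= 2 (default 4).
#' @param scale_segment_len window length in samples for median-based
#'   scaling (default 4096).
#' @param max_sample_gap_s maximum tolerated gap between consecutive
#'   timestamps, seconds (default 0.05).
#' @return a validated list of class `PreprocessParams`.
#' @export
preprocessParams <- function(target_fs = 200, hp_cutoff_hz = 2,
                             hp_order = 4, scale_segment_len = 4096,
                             max_sample_gap_s = 0.05) {
  p <- list(target_fs = stopIfNot1(target_fs, "target_fs", 1e-9),
            hp_cutoff_hz = stopIfNot1(hp_cutoff_hz, "hp_cutoff_hz", 1e-9),
            hp_order = stopIfNot1(hp_order, "hp_order", 2),
            scale_segment_len = stopIfNot1(scale_segment_len,
                                           "scale_segment_len", 2),
            max_sample_gap_s = stopIfNot1(max_sample_gap_s,
                                          "max_sample_gap_s", 0))
  if (p$target_fs <= 2 * p$hp_cutoff_hz)
    stop("invalid configuration: 'target_fs' must exceed twice 'hp_cutoff_hz'",
         call. = FALSE)
  if (p$hp_order %% 2 != 0)
    stop("invalid configuration: 'hp_order' must be even", call. = FALSE)
  class(p) <- "PreprocessParams"
  p
}

#' Resample a recording to a uniform target rate
#'
#' Linear interpolation onto the new uniform grid. When downsampling, a
#' 4th-order zero-phase Butterworth low-pass at 0.45 x target rate is
#' applied first as an anti-alias guard; upsampling interpolates
#' directly.
#'
#' @param rec an [ScgRecording-class] with at least 2 samples.
#' @param target_fs target sampling rate in Hz.
#' @return an [ScgRecording-class] at `target_fs` covering the same time
#'   span (within one output sample).
#' @export
resampleRecording <- function(rec, target_fs) {
  stopifnot(is(rec, "ScgRecording"))
  target_fs <- stopIfNot1(target_fs, "target_fs", 1e-9)
  n <- nSamples(rec)
  if (n < 2L) stop("cannot resample a single-sample recording")
  fs <- samplingRate(rec)
  if (isTRUE(all.equal(fs, target_fs))) return(rec)
  sig <- scgSignal(rec)
  if (target_fs < fs) {
    lp <- signal::butter(4, 0.45 * target_fs / (fs / 2), type = "low")
    sig <- apply(sig, 2, function(ch) .filtfiltPad(lp, ch, fs, 0.45 * target_fs))
  }
  told <- sampleTimes(n, fs, timeOrigin(rec))
  n_new <- floor((n - 1L) / fs * target_fs) + 1L
  tnew <- sampleTimes(n_new, target_fs, timeOrigin(rec))
  out <- apply(sig, 2, function(ch) approx(told, ch, xout = tnew)$y)
  scgRecording(matrix(out, n_new), fs = target_fs, t0 = timeOrigin(rec),
               channelNames = rec@channelNames)
}

# Zero-phase (forward-backward) filtering with odd-reflection padding of
# 3 cutoff periods at each end, which keeps edge transients off the data.
.filtfiltPad <- function(flt, x, fs, cutoff_hz) {
  n <- length(x)
  pad <- min(n - 1L, ceiling(3 * fs / cutoff_hz))
  if (pad > 0) {
    head_pad <- 2 * x[1] - x[(pad + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
    y <- signal::filtfilt(flt, c(head_pad, x, tail_pad))
    y[(pad + 1):(pad + n)]
  } else {
    signal::filtfilt(flt, x)
  }
}

#' Zero-phase high-pass filter a recording
#'
#' Removes sub-cardiac low-frequency content (respiratory motion,
#' posture drift) with an `hp_order`-order Butterworth high-pass at
#' `hp_cutoff_hz`, applied forward and backward so events keep their
#' timing (zero phase). The doubled effective attenuation of the
#' two-pass application is accepted.
#'
#' @param rec an [ScgRecording-class]; must be longer than the filter
#'   warm-up (3 x order samples).
#' @param params a [preprocessParams()] object.
#' @return the filtered [ScgRecording-class].
#' @export
highpassRecording <- function(rec, params = preprocessParams()) {
  stopifnot(is(rec, "ScgRecording"))
  fs <- samplingRate(rec)
  if (nSamples(rec) < 3 * params$hp_order)
    stop("recording shorter than the filter warm-up (3 x order samples)")
  if (params$hp_cutoff_hz >= fs / 2)
    stop("high-pass cutoff must be below the Nyquist frequency")
  hp <- signal::butter(params$hp_order, params$hp_cutoff_hz / (fs / 2),
                       type = "high")
  out <- apply(scgSignal(rec), 2, function(ch)
    .filtfiltPad(hp, ch, fs, params$hp_cutoff_hz))
  scgRecording(matrix(out, nSamples(rec)), fs = fs, t0 = timeOrigin(rec),
               channelNames = rec@channelNames)
}

#' Median-based robust amplitude scaling
#'
#' Per channel, the recording is partitioned into consecutive windows of
#' `scale_segment_len` samples (a final partial window is included when
#' at least half length). The median of the window minima `m` and the
#' median of the window maxima `M` define stable global bounds; the
#' channel is mapped affinely so `[m, M] -> [-1, 1]` and clipped to
#' `[-1.5, 1.5]`. A flat channel (`M == m`) maps to zero with a warning.
#'
#' @param rec an [ScgRecording-class].
#' @param params a [preprocessParams()] object.
#' @return the scaled [ScgRecording-class].
#' @export
medianScale <- function(rec, params = preprocessParams()) {
  stopifnot(is(rec, "ScgRecording"))
  n <- nSamples(rec)
  L <- as.integer(params$scale_segment_len)
  out <- apply(scgSignal(rec), 2, function(ch) {
    if (n < L) {
      m <- min(ch); M <- max(ch)
    } else {
      starts <- seq(1L, n, by = L)
      mins <- numeric(0); maxs <- numeric(0)
      for (s in starts) {
        e <- min(s + L - 1L, n)
        if (e - s + 1L >= L / 2) {          # drop short trailing remnant
          w <- ch[s:e]
          mins <- c(mins, min(w)); maxs <- c(maxs, max(w))
        }
      }
      m <- median(mins); M <- median(maxs)
    }
    if (M == m) {
      warning("flat channel: mapped to zero", call. = FALSE)
      rep(0, n)
    } else {
      pmin(pmax(2 * (ch - m) / (M - m) - 1, -1.5), 1.5)
    }
  })
  scgRecording(matrix(out, n), fs = samplingRate(rec), t0 = timeOrigin(rec),
               channelNames = rec@channelNames)
}

#' Validate sample-gap continuity of a timestamp sequence
#'
#' Splits a monotone timestamp sequence into maximal runs of samples
#' whose preceding inter-sample gap does not exceed `max_gap_s`, the
#' validity rule applied to non-uniformly delivered wrist-worn data.
#'
#' @param timestamps strictly increasing sample times in seconds.
#' @param max_gap_s maximum tolerated gap in seconds (default 0.05).
#' @return integer matrix with columns `start`, `end`: half-open 1-based
#'   index runs (a run covers samples `start` to `end - 1`), maximal and
#'   disjoint, jointly covering all samples.
#' @export
validateGaps <- function(timestamps, max_gap_s = 0.05) {
  timestamps <- as.numeric(timestamps)
  n <- length(timestamps)
  if (n == 0L)
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end"))))
  d <- diff(timestamps)
  if (any(d <= 0)) stop("timestamps must be strictly increasing")
  breaks <- which(d > max_gap_s)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n) + 1L        # half-open
  matrix(c(starts, ends), ncol = 2,
         dimnames = list(NULL, c("start", "end")))
}
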