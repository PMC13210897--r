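#' @import methods
#' @importFrom stats approx median quantile rnorm runif rpois sd cor fft
#' @importFrom utils head tail read.table write.table
#' @useDynLib scgbeat, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' ScgRecording: a uniformly sampled tri-axial acceleration signal
#'
#' Container for a seismocardiography (SCG) recording: three ordered
#' channels of acceleration samples (arbitrary units) on a uniform time
#' grid, with a sampling rate and a time origin.
#'
#' @slot signal numeric matrix, samples x channels (3 columns: x, y, z).
#' @slot fs sampling rate in Hz.
#' @slot t0 time of the first sample in seconds.
#' @slot channelNames character vector of channel identifiers.
#'
#' @seealso [scgRecording()] for the constructor.
#' @exportClass ScgRecording
setClass("ScgRecording",
  representation(signal = "matrix", fs = "numeric", t0 = "numeric",
                 channelNames = "character"),
  prototype(signal = matrix(0, 1, 3), fs = 200, t0 = 0,
            channelNames = c("x", "y", "z")))

setValidity("ScgRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@signal)) msg <- c(msg, "signal must be numeric")
  if (nrow(object@signal) < 1L) msg <- c(msg, "recording must contain at least one sample")
  if (ncol(object@signal) != length(object@channelNames))
    msg <- c(msg, "number of channels must match channelNames")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (anyNA(object@signal)) msg <- c(msg, "signal must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct an ScgRecording
#'
#' @param signal numeric matrix (samples x channels) or data.frame with one
#'   column per channel.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds (default 0).
#' @param channelNames channel identifiers; defaults to `x`, `y`, `z` for
#'   three channels.
#' @return an [ScgRecording-class] object.
#' @examples
#' rec <- scgRecording(matrix(rnorm(600), ncol = 3), fs = 200)
#' nSamples(rec)
#' @export
scgRecording <- function(signal, fs, t0 = 0,
                         channelNames = NULL) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  dimnames(signal) <- NULL             # channel names live in channelNames
  if (is.null(channelNames)) {
    channelNames <- if (ncol(signal) == 3L) c("x", "y", "z")
                    else paste0("ch", seq_len(ncol(signal)))
  }
  new("ScgRecording", signal = signal, fs = as.numeric(fs),
      t0 = as.numeric(t0), channelNames = channelNames)
}

#' BeatAnnotation: ordered heartbeat event times
#'
#' Strictly increasing heartbeat times, in seconds, on a recording's
#' timeline.
#'
#' @slot times numeric vector of strictly increasing, non-negative event
#'   times in seconds.
#' @exportClass BeatAnnotation
setClass("BeatAnnotation", representation(times = "numeric"),
         prototype(times = numeric()))

setValidity("BeatAnnotation", function(object) {
  t <- object@times
  if (anyNA(t)) return("beat times must not contain NA")
  if (length(t) && any(t < 0)) return("beat times must be non-negative")
  if (length(t) > 1L && any(diff(t) <= 0))
    return("beat times must be strictly increasing")
  TRUE
})

#' Construct a BeatAnnotation
#'
#' @param times numeric vector of beat times in seconds (strictly
#'   increasing, non-negative).
#' @return a [BeatAnnotation-class] object.
#' @export
beatAnnotation <- function(times = numeric()) {
  new("BeatAnnotation", times = as.numeric(times))
}

#' SampleMask: per-sample heartbeat label or probability sequence
#'
#' Binary ground-truth labels or predicted heartbeat-class probabilities,
#' one value per sample, aligned to a recording's time grid.
#'
#' @slot values numeric vector in \[0, 1\].
#' @slot fs sampling rate in Hz.
#' @slot t0 time of the first sample in seconds.
#' @exportClass SampleMask
setClass("SampleMask",
  representation(values = "numeric", fs = "numeric", t0 = "numeric"),
  prototype(values = 0, fs = 200, t0 = 0))

setValidity("SampleMask", function(object) {
  v <- object@values
  if (length(v) < 1L) return("mask must contain at least one sample")
  if (anyNA(v)) return("mask values must not contain NA")
  if (any(v < 0 | v > 1)) return("mask values must lie in [0, 1]")
  if (object@fs <= 0) return("fs must be positive")
  TRUE
})

#' Construct a SampleMask
#'
#' @param values numeric vector of per-sample values in \[0, 1\].
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @return a [SampleMask-class] object.
#' @export
sampleMask <- function(values, fs, t0 = 0) {
  new("SampleMask", values = as.numeric(values), fs = as.numeric(fs),
      t0 = as.numeric(t0))
}

#' RrSeries: reference RR intervals
#'
#' Ordered beat-to-beat RR intervals in milliseconds, anchored on the
#' recording timeline by the time of the beat preceding the first interval.
#'
#' @slot intervalsMs numeric vector of RR intervals in milliseconds.
#' @slot anchorS time (seconds) of the beat preceding the first interval.
#' @exportClass RrSeries
setClass("RrSeries",
  representation(intervalsMs = "numeric", anchorS = "numeric"),
  prototype(intervalsMs = numeric(), anchorS = 0))

setValidity("RrSeries", function(object) {
  iv <- object@intervalsMs
  if (anyNA(iv)) return("intervals must not contain NA")
  if (length(iv) && any(iv <= 0)) return("RR intervals must be positive")
  if (object@anchorS < 0) return("anchorS must be non-negative")
  TRUE
})

#' Construct an RrSeries
#'
#' Physiological validation restricts intervals to \[200, 3000\] ms
#' (20--300 bpm); out-of-range intervals raise an error unless
#' `validate = FALSE`.
#'
#' @param intervalsMs RR intervals in milliseconds.
#' @param anchorS time (seconds) of the beat preceding the first interval.
#' @param validate enforce the \[200, 3000\] ms physiological range.
#' @return an [RrSeries-class] object.
#' @export
rrSeries <- function(intervalsMs, anchorS = 0, validate = TRUE) {
  intervalsMs <- as.numeric(intervalsMs)
  if (length(intervalsMs) && any(intervalsMs <= 0))
    stop("RR intervals must be positive")
  if (validate && length(intervalsMs) &&
      any(intervalsMs < 200 | intervalsMs > 3000))
    stop("RR intervals outside the physiological range [200, 3000] ms; ",
         "use validate = FALSE to bypass")
  new("RrSeries", intervalsMs = intervalsMs, anchorS = as.numeric(anchorS))
}

#' IbiSeries: inter-beat intervals with per-interval quality flags
#'
#' @slot onsets numeric vector: start time (seconds) of each interval.
#' @slot intervals numeric vector: interval durations in seconds.
#' @slot flags character vector: one of `good`, `corrected`, `excluded`
#'   per interval.
#' @exportClass IbiSeries
setClass("IbiSeries",
  representation(onsets = "numeric", intervals = "numeric",
                 flags = "character"),
  prototype(onsets = numeric(), intervals = numeric(), flags = character()))

setValidity("IbiSeries", function(object) {
  n <- length(object@intervals)
  if (length(object@onsets) != n || length(object@flags) != n)
    return("onsets, intervals and flags must have equal length")
  if (n && any(object@intervals <= 0)) return("intervals must be positive")
  if (n > 1L && any(diff(object@onsets) <= 0))
    return("onsets must be strictly increasing")
  if (n && !all(object@flags %in% c("good", "corrected", "excluded")))
    return("flags must be one of good, corrected, excluded")
  TRUE
})

#' Construct an IbiSeries
#'
#' @param onsets start times in seconds, one per interval.
#' @param intervals durations in seconds.
#' @param flags per-interval quality flag (`good`, `corrected`,
#'   `excluded`); defaults to all `good`.
#' @return an [IbiSeries-class] object.
#' @export
ibiSeries <- function(onsets, intervals,
                      flags = rep("good", length(intervals))) {
  new("IbiSeries", onsets = as.numeric(onsets),
      intervals = as.numeric(intervals), flags = as.character(flags))
}

#' HrSeries: windowed heart-rate estimates with quality gating
#'
#' @slot windowCenters numeric: window centre times in seconds.
#' @slot hrBpm numeric: heart rate per window in beats/min, `NA` where the
#'   effective-length quality gate failed.
#' @slot effectiveFraction numeric in \[0, 1\]: fraction of the window
#'   covered by good-quality intervals.
#' @exportClass HrSeries
setClass("HrSeries",
  representation(windowCenters = "numeric", hrBpm = "numeric",
                 effectiveFraction = "numeric"),
  prototype(windowCenters = numeric(), hrBpm = numeric(),
            effectiveFraction = numeric()))

setValidity("HrSeries", function(object) {
  n <- length(object@windowCenters)
  if (length(object@hrBpm) != n || length(object@effectiveFraction) != n)
    return("windowCenters, hrBpm and effectiveFraction must have equal length")
  ef <- object@effectiveFraction
  if (n && any(ef < 0 | ef > 1)) return("effectiveFraction must lie in [0, 1]")
  TRUE
})

#' Construct an HrSeries
#'
#' @param windowCenters window centre times in seconds.
#' @param hrBpm heart rate per window (beats/min), `NA` where undefined.
#' @param effectiveFraction per-window effective-length fraction.
#' @return an [HrSeries-class] object.
#' @export
hrSeries <- function(windowCenters, hrBpm, effectiveFraction) {
  new("HrSeries", windowCenters = as.numeric(windowCenters),
      hrBpm = as.numeric(hrBpm),
      effectiveFraction = as.numeric(effectiveFraction))
}

#' MatchResult: one-to-one pairing of predicted vs reference beats
#'
#' @slot pairs numeric matrix with columns `pred` and `ref` (times in
#'   seconds), one row per matched pair.
#' @slot tp,fp,fn integer tallies of true positives, false positives and
#'   false negatives.
#' @slot tolerance matching tolerance in seconds.
#' @exportClass MatchResult
setClass("MatchResult",
  representation(pairs = "matrix", tp = "integer", fp = "integer",
                 fn = "integer", tolerance = "numeric"),
  prototype(pairs = matrix(numeric(), 0, 2,
                           dimnames = list(NULL, c("pred", "ref"))),
            tp = 0L, fp = 0L, fn = 0L, tolerance = 0.1))

setValidity("MatchResult", function(object) {
  if (object@tp != nrow(object@pairs)) return("tp must equal the number of pairs")
  if (object@fp < 0 || object@fn < 0) return("fp and fn must be non-negative")
  if (nrow(object@pairs) &&
      any(abs(object@pairs[, 1] - object@pairs[, 2]) >
          object@tolerance + 1e-12))
    return("all pairs must lie within the matching tolerance")
  TRUE
})
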