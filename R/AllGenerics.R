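#' Accessors for scgbeat classes
#'
#' Small accessor generics shared across the package's S4 containers.
#'
#' @param x an scgbeat object.
#' @return the corresponding slot value.
#' @name scgbeat-accessors
NULL

#' @rdname scgbeat-accessors
#' @export
setGeneric("scgSignal", function(x) standardGeneric("scgSignal"))
#' @rdname scgbeat-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname scgbeat-accessors
#' @export
setGeneric("timeOrigin", function(x) standardGeneric("timeOrigin"))
#' @rdname scgbeat-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname scgbeat-accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname scgbeat-accessors
#' @export
setGeneric("beatTimes", function(x) standardGeneric("beatTimes"))
#' @rdname scgbeat-accessors
#' @export
setGeneric("maskValues", function(x) standardGeneric("maskValues"))
#' @rdname scgbeat-accessors
#' @export
setGeneric("ibiOnsets", function(x) standardGeneric("ibiOnsets"))
#' @rdname scgbeat-accessors
#' @export
setGeneric("ibiIntervals", function(x) standardGeneric("ibiIntervals"))
#' @rdname scgbeat-accessors
#' @export
setGeneric("ibiFlags", function(x) standardGeneric("ibiFlags"))
#' @rdname scgbeat-accessors
#' @export
setGeneric("hrValues", function(x) standardGeneric("hrValues"))
#' @rdname scgbeat-accessors
#' @export
setGeneric("windowCenters", function(x) standardGeneric("windowCenters"))
#' @rdname scgbeat-accessors
#' @export
setGeneric("effectiveFraction", function(x) standardGeneric("effectiveFraction"))

#' @rdname scgbeat-accessors
#' @export
setMethod("scgSignal", "ScgRecording", function(x) x@signal)
#' @rdname scgbeat-accessors
#' @export
setMethod("samplingRate", "ScgRecording", function(x) x@fs)
#' @rdname scgbeat-accessors
#' @export
setMethod("samplingRate", "SampleMask", function(x) x@fs)
#' @rdname scgbeat-accessors
#' @export
setMethod("timeOrigin", "ScgRecording", function(x) x@t0)
#' @rdname scgbeat-accessors
#' @export
setMethod("timeOrigin", "SampleMask", function(x) x@t0)
#' @rdname scgbeat-accessors
#' @export
setMethod("nSamples", "ScgRecording", function(x) nrow(x@signal))
#' @rdname scgbeat-accessors
#' @export
setMethod("nSamples", "SampleMask", function(x) length(x@values))
#' @rdname scgbeat-accessors
#' @export
setMethod("duration", "ScgRecording", function(x) nrow(x@signal) / x@fs)
#' @rdname scgbeat-accessors
#' @export
setMethod("duration", "SampleMask", function(x) length(x@values) / x@fs)
#' @rdname scgbeat-accessors
#' @export
setMethod("beatTimes", "BeatAnnotation", function(x) x@times)
#' @rdname scgbeat-accessors
#' @export
setMethod("maskValues", "SampleMask", function(x) x@values)
#' @rdname scgbeat-accessors
#' @export
setMethod("ibiOnsets", "IbiSeries", function(x) x@onsets)
#' @rdname scgbeat-accessors
#' @export
setMethod("ibiIntervals", "IbiSeries", function(x) x@intervals)
#' @rdname scgbeat-accessors
#' @export
setMethod("ibiFlags", "IbiSeries", function(x) x@flags)
#' @rdname scgbeat-accessors
#' @export
setMethod("hrValues", "HrSeries", function(x) x@hrBpm)
#' @rdname scgbeat-accessors
#' @export
setMethod("windowCenters", "HrSeries", function(x) x@windowCenters)
#' @rdname scgbeat-accessors
#' @export
setMethod("effectiveFraction", "HrSeries", function(x) x@effectiveFraction)

#' @rdname scgbeat-accessors
#' @export
setMethod("length", "BeatAnnotation", function(x) length(x@times))
#' @rdname scgbeat-accessors
#' @export
setMethod("length", "IbiSeries", function(x) length(x@intervals))
#' @rdname scgbeat-accessors
#' @export
setMethod("length", "HrSeries", function(x) length(x@windowCenters))

setMethod("show", "ScgRecording", function(object) {
  cat(sprintf("ScgRecording: %d samples x %d channels (%s) @ %g Hz, %.2f s, t0 = %g s\n",
              nrow(object@signal), ncol(object@signal),
              paste(object@channelNames, collapse = ","),
              object@fs, nrow(object@signal) / object@fs, object@t0))
})

setMethod("show", "BeatAnnotation", function(object) {
  n <- length(object@times)
  cat(sprintf("BeatAnnotation: %d beats", n))
  if (n) cat(sprintf(" in [%.3f, %.3f] s", object@times[1], object@times[n]))
  cat("\n")
})

setMethod("show", "SampleMask", function(object) {
  cat(sprintf("SampleMask: %d samples @ %g Hz, values in [%.3g, %.3g]\n",
              length(object@values), object@fs,
              min(object@values), max(object@values)))
})

setMethod("show", "IbiSeries", function(object) {
  tab <- table(factor(object@flags, c("good", "corrected", "excluded")))
  cat(sprintf("IbiSeries: %d intervals (good %d, corrected %d, excluded %d)\n",
              length(object@intervals), tab[["good"]], tab[["corrected"]],
              tab[["excluded"]]))
})

setMethod("show", "HrSeries", function(object) {
  def <- sum(!is.na(object@hrBpm))
  cat(sprintf("HrSeries: %d windows, %d with defined HR", length(object@windowCenters), def))
  if (def) cat(sprintf(", mean %.1f bpm", mean(object@hrBpm, na.rm = TRUE)))
  cat("\n")
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: TP %d, FP %d, FN %d (tolerance %.3g s)\n",
              object@tp, object@fp, object@fn, object@tolerance))
})

#' Tallies of a MatchResult
#'
#' @param x a [MatchResult-class].
#' @return named integer vector with elements `tp`, `fp`, `fn`.
#' @export
matchCounts <- function(x) {
  stopifnot(is(x, "MatchResult"))
  c(tp = x@tp, fp = x@fp, fn = x@fn)
}

#' Matched beat pairs of a MatchResult
#'
#' @param x a [MatchResult-class].
#' @return two-column matrix (`pred`, `ref`) of matched times in seconds.
#' @export
matchPairs <- function(x) {
  stopifnot(is(x, "MatchResult"))
  x@pairs
}
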