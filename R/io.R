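# Columnar text readers/writers for recordings, beats, RR streams,
# masks, HR series and artifact flags. All formats are plain text so
# fixtures stay portable and diffable.

#' Read / write a recording as columnar text
#'
#' Format: tab-separated columns `time_s, x, y, z` with a header line.
#' The time column must be uniform; the sampling rate is recovered from
#' the median time step.
#'
#' @param rec an [ScgRecording-class].
#' @param path file path.
#' @return `readRecording` returns an [ScgRecording-class];
#'   `writeRecording` returns `path` invisibly.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "ScgRecording"))
  df <- data.frame(time_s = sampleTimes(nSamples(rec), samplingRate(rec),
                                        timeOrigin(rec)),
                   scgSignal(rec))
  names(df) <- c("time_s", rec@channelNames)
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (ncol(df) < 2L) stop("recording file needs a time column and channels")
  dt <- diff(df[[1]])
  if (any(dt <= 0)) stop("time column must be strictly increasing")
  fs <- 1 / median(dt)
  scgRecording(as.matrix(df[, -1, drop = FALSE]), fs = fs, t0 = df[[1]][1],
               channelNames = names(df)[-1])
}

#' Read / write beat annotations
#'
#' One beat time (seconds) per line.
#'
#' @param beats a [BeatAnnotation-class].
#' @param path file path.
#' @return `readBeats` returns a [BeatAnnotation-class].
#' @export
writeBeats <- function(beats, path) {
  stopifnot(is(beats, "BeatAnnotation"))
  writeLines(format(beatTimes(beats), digits = 12, trim = TRUE,
                    scientific = FALSE), path)
  invisible(path)
}

#' @rdname writeBeats
#' @export
readBeats <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(trimws(x))]
  beatAnnotation(as.numeric(x))
}

#' Read an RR-interval file
#'
#' One interval (milliseconds) per line; an optional header line
#' `# anchor_s <value>` carries the timeline anchor.
#'
#' @param path file path.
#' @param validate enforce the physiological interval range.
#' @return an [RrSeries-class].
#' @export
readRr <- function(path, validate = TRUE) {
  lines <- readLines(path)
  anchor <- 0
  hdr <- grepl("^#", lines)
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("anchor_s\\s+([0-9.eE+-]+)", h))[[1]]
    if (length(m) == 2L) anchor <- as.numeric(m[2])
  }
  vals <- lines[!hdr & nzchar(trimws(lines))]
  rrSeries(as.numeric(vals), anchorS = anchor, validate = validate)
}

#' @rdname readRr
#' @param rr an [RrSeries-class].
#' @export
writeRr <- function(rr, path) {
  stopifnot(is(rr, "RrSeries"))
  writeLines(c(sprintf("# anchor_s %.9g", rr@anchorS),
               format(rr@intervalsMs, digits = 12, trim = TRUE,
                      scientific = FALSE)), path)
  invisible(path)
}

#' Read / write a sample mask as run-length text
#'
#' Header line `# fs <Hz> t0 <s> n <samples>`, then one `start end value`
#' triple per run (half-open 0-based sample runs of constant value);
#' zero runs are omitted.
#'
#' @param mask a [SampleMask-class].
#' @param path file path.
#' @return `readMask` returns a [SampleMask-class].
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "SampleMask"))
  v <- maskValues(mask)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  lines <- sprintf("%d %d %.10g", starts[keep], ends[keep], r$values[keep])
  writeLines(c(sprintf("# fs %.10g t0 %.10g n %d", samplingRate(mask),
                       timeOrigin(mask), length(v)), lines), path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  lines <- readLines(path)
  hdr <- regmatches(lines[1],
                    regexec("# fs ([0-9.eE+-]+) t0 ([0-9.eE+-]+) n (\\d+)",
                            lines[1]))[[1]]
  if (length(hdr) != 4L) stop("malformed mask header")
  fs <- as.numeric(hdr[2]); t0 <- as.numeric(hdr[3]); n <- as.integer(hdr[4])
  v <- numeric(n)
  for (ln in lines[-1]) {
    if (!nzchar(trimws(ln))) next
    f <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    v[(f[1] + 1L):f[2]] <- f[3]
  }
  sampleMask(v, fs = fs, t0 = t0)
}

#' Write a windowed HR series as CSV
#'
#' Columns: `window_center_s, hr_bpm, effective_fraction`.
#'
#' @param hr an [HrSeries-class].
#' @param path file path.
#' @return `readHr` returns an [HrSeries-class].
#' @export
writeHr <- function(hr, path) {
  stopifnot(is(hr, "HrSeries"))
  df <- data.frame(window_center_s = windowCenters(hr),
                   hr_bpm = hrValues(hr),
                   effective_fraction = effectiveFraction(hr))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHr
#' @export
readHr <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",")
  hrSeries(df$window_center_s, df$hr_bpm, df$effective_fraction)
}

#' Write artifact flags as BED-like interval text
#'
#' Columns: `start_s, end_s, flagged (0/1), energy`.
#'
#' @param flags an `ArtifactFlags` object from [flagArtifacts()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeArtifactFlags <- function(flags, path) {
  stopifnot(inherits(flags, "ArtifactFlags"))
  df <- data.frame(start_s = flags$segment_bounds_s[, 1],
                   end_s = flags$segment_bounds_s[, 2],
                   flagged = as.integer(flags$flags),
                   energy = flags$energies)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
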