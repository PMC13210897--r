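#' Per-segment STFT spectral energy
#'
#' Divides a recording into consecutive `seg_len_s` segments (a final
#' partial segment is dropped) and computes, per segment, the summed
#' squared STFT magnitudes within `band_hz`, accumulated over the three
#' channels. The STFT uses a 1 s Hann window with 50% overlap.
#'
#' @param rec an [ScgRecording-class]. A recording shorter than one
#'   segment is treated as a single whole-recording segment with a
#'   warning.
#' @param seg_len_s segment length in seconds (default 10).
#' @param band_hz length-2 frequency band in Hz (default `c(2, 25)`).
#' @param stft_window_s STFT window length in seconds (default 1).
#' @param stft_overlap fractional window overlap (default 0.5).
#' @return numeric vector of segment energies, with a `"bounds"`
#'   attribute holding the `(start_s, end_s)` matrix of segment bounds.
#' @export
segmentSpectralEnergy <- function(rec, seg_len_s = 10, band_hz = c(2, 25),
                                  stft_window_s = 1, stft_overlap = 0.5) {
  stopifnot(is(rec, "ScgRecording"))
  fs <- samplingRate(rec)
  n <- nSamples(rec)
  seg_n <- round(seg_len_s * fs)
  if (n < seg_n) {
    warning("recording shorter than one segment; using a single segment",
            call. = FALSE)
    seg_n <- n
  }
  n_seg <- n %/% seg_n
  win_n <- max(round(stft_window_s * fs), 2)
  hop <- max(round(win_n * (1 - stft_overlap)), 1)
  w <- .hann(win_n)
  freqs <- (seq_len(win_n) - 1L) / win_n * fs
  # half-open band (low, high]: content at exactly the high-pass cutoff
  # belongs to the stop band, so the edge bin is excluded
  band <- freqs > band_hz[1] & freqs <= band_hz[2] & freqs <= fs / 2
  sig <- scgSignal(rec)
  energies <- numeric(n_seg)
  for (s in seq_len(n_seg)) {
    i0 <- (s - 1L) * seg_n
    starts <- seq(1L, seg_n - win_n + 1L, by = hop)
    e <- 0
    for (ch in seq_len(ncol(sig))) {
      x <- sig[(i0 + 1L):(i0 + seg_n), ch]
      for (st in starts) {
        X <- fft(x[st:(st + win_n - 1L)] * w)
        e <- e + sum(Mod(X[band])^2)
      }
    }
    energies[s] <- e
  }
  bounds <- cbind(start_s = (seq_len(n_seg) - 1L) * seg_n / fs,
                  end_s = seq_len(n_seg) * seg_n / fs) + timeOrigin(rec)
  attr(energies, "bounds") <- bounds
  energies
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

#' Flag motion-corrupted segments by relative spectral energy
#'
#' A segment is flagged as a movement artifact when its spectral energy
#' strictly exceeds `ratio_threshold` times the minimum segment energy
#' of the same recording. Recordings with fewer than two segments cannot
#' self-normalize and yield no flags (with a warning).
#'
#' @param energies numeric vector of segment energies from
#'   [segmentSpectralEnergy()] (its `"bounds"` attribute, when present,
#'   is carried into the result).
#' @param ratio_threshold flagging ratio, strict comparison (default 5).
#' @return an object of class `ArtifactFlags`: a list with
#'   `segment_bounds_s` (matrix), `energies`, `flags` (logical) and
#'   `ratio_threshold`.
#' @examples
#' flagArtifacts(c(1, 1, 6))$flags   # FALSE FALSE TRUE
#' @export
flagArtifacts <- function(energies, ratio_threshold = 5) {
  bounds <- attr(energies, "bounds")
  energies <- as.numeric(energies)
  if (is.null(bounds))
    bounds <- matrix(NA_real_, length(energies), 2,
                     dimnames = list(NULL, c("start_s", "end_s")))
  if (length(energies) == 0L) {
    flags <- logical(0)
  } else if (length(energies) < 2L) {
    warning("fewer than two segments: cannot self-normalize, no flags",
            call. = FALSE)
    flags <- rep(FALSE, length(energies))
  } else {
    flags <- energies > ratio_threshold * min(energies)
  }
  structure(list(segment_bounds_s = bounds, energies = energies,
                 flags = flags, ratio_threshold = ratio_threshold),
            class = "ArtifactFlags")
}

#' @export
print.ArtifactFlags <- function(x, ...) {
  cat(sprintf("ArtifactFlags: %d segments, %d flagged (ratio > %g x min energy)\n",
              length(x$flags), sum(x$flags), x$ratio_threshold))
  invisible(x)
}
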