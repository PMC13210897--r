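# Independent reference implementations used to cross-check the package's
# algorithms, plus small fixture builders. These deliberately use plain
# per-sample / exhaustive logic rather than the package's vectorized paths.

rms <- function(x) sqrt(mean(x^2))

# Exhaustive per-sample reference for probability-mask beat localization
# (no resampling: the mask is assumed to already be on the target grid).
bruteLocalize <- function(v, fs, prob_threshold = 0.8,
                          min_width = 160, min_sep_s = 0.55) {
  runs <- list()
  start <- NA
  for (i in seq_along(v)) {
    if (v[i] > prob_threshold && is.na(start)) start <- i
    if ((v[i] <= prob_threshold || i == length(v)) && !is.na(start)) {
      end <- if (v[i] > prob_threshold) i else i - 1L
      runs[[length(runs) + 1L]] <- c(start, end)
      start <- NA
    }
  }
  if (!length(runs)) return(numeric())
  runs <- runs[vapply(runs, function(r) r[2] - r[1] + 1L >= min_width,
                      logical(1))]
  if (!length(runs)) return(numeric())
  times <- vapply(runs, function(r) mean(r[1]:r[2] - 1) / fs, numeric(1))
  score <- vapply(runs, function(r) mean(v[r[1]:r[2]]), numeric(1))
  repeat {
    if (length(times) < 2L) break
    gaps <- diff(times)
    j <- which(gaps < min_sep_s)[1]
    if (is.na(j)) break
    drop <- if (score[j + 1L] > score[j]) j else j + 1L
    times <- times[-drop]; score <- score[-drop]
  }
  times
}

# Exhaustive maximum-cardinality one-to-one matching within tolerance
# (recursion over predictions; feasible for <= ~12 beats).
bruteMaxMatch <- function(pred, ref, tol) {
  best <- 0L
  recurse <- function(i, used) {
    if (i > length(pred)) return(0L)
    b <- recurse(i + 1L, used)               # leave pred i unmatched
    for (j in seq_along(ref)) {
      if (!used[j] && abs(pred[i] - ref[j]) <= tol) {
        used2 <- used; used2[j] <- TRUE
        b <- max(b, 1L + recurse(i + 1L, used2))
      }
    }
    b
  }
  recurse(1L, rep(FALSE, length(ref)))
}

# Naive agreement statistics written directly from the defining formulas.
bruteAgreement <- function(e, r) {
  d <- e - r
  n <- length(d)
  bias <- sum(d) / n
  s <- sqrt(sum((d - bias)^2) / (n - 1))
  list(mae = sum(abs(d)) / n, rmse = sqrt(sum(d^2) / n),
       r = sum((e - mean(e)) * (r - mean(r))) /
         sqrt(sum((e - mean(e))^2) * sum((r - mean(r))^2)),
       bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s), see = s)
}

# Single-channel recording from a numeric vector.
vecRecording <- function(x, fs, t0 = 0) {
  scgRecording(matrix(x, ncol = 1), fs = fs, t0 = t0, channelNames = "x")
}

# Tri-channel recording with identical channels.
triRecording <- function(x, fs, t0 = 0) {
  scgRecording(cbind(x, x, x), fs = fs, t0 = t0)
}
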