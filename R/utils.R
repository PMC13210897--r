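# Internal helpers shared across modules.

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so no global state leaks.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Sample times of a recording-like object (t0 + k/fs, k = 0..n-1).
sampleTimes <- function(n, fs, t0 = 0) t0 + (seq_len(n) - 1L) / fs

stopIfNot1 <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop(sprintf("invalid configuration: '%s' must be a single value in [%g, %g]",
                 name, min, max), call. = FALSE)
  as.numeric(x)
}
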