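#' Simulation configuration for synthetic tri-axial SCG
#'
#' Defines the generative model used by [simulateBeatTimes()] and
#' [simulateScg()]: a slowly varying heart rate with respiratory sinus
#' arrhythmia (RSA) and white beat-to-beat jitter drives quasi-periodic
#' per-axis beat wavelets (exponentially decaying sinusoids in the
#' 10--25 Hz cardiomechanical band), superimposed on a sub-2-Hz
#' respiration baseline with multiplicative amplitude modulation, plus
#' broadband Gaussian sensor noise at a configurable signal-to-noise
#' ratio. A fraction of beats carries a second, smaller wavelet
#' (dual-peak morphology).
#'
#' @param duration_s recording length in seconds (>= 0; 0 yields empty
#'   outputs).
#' @param fs sampling rate in Hz (>= 50).
#' @param mean_hr_bpm mean heart rate, beats/min, in \[30, 180\].
#' @param hr_sd_bpm stationary standard deviation (beats/min) of the slow
#'   mean-reverting random walk on heart rate.
#' @param rsa_amp_ms amplitude (ms) of the sinusoidal RSA modulation of
#'   the RR intervals at `resp_freq_hz`.
#' @param resp_freq_hz respiration frequency in Hz (< 2).
#' @param jitter_ms standard deviation (ms) of white beat-to-beat jitter.
#' @param carrier_freq_hz per-axis wavelet carrier frequencies (Hz),
#'   length 3.
#' @param decay_tau_s per-axis wavelet decay time constants (s), length 3.
#' @param amplitude per-axis wavelet amplitudes (arbitrary units),
#'   length 3.
#' @param noise_snr_db sensor-noise level: SNR in dB of the beat-wavelet
#'   component relative to the added Gaussian noise (`Inf` = noiseless).
#' @param resp_amp amplitude of the additive respiration baseline,
#'   relative units (scaled per axis by `amplitude`).
#' @param am_depth depth in \[0, 1\] of the multiplicative respiratory
#'   amplitude modulation of beat wavelets.
#' @param dual_peak_prob probability in \[0, 1\] that a beat carries a
#'   second wavelet.
#' @param dual_peak_offset_s delay (s) of the secondary wavelet.
#' @param dual_peak_ratio amplitude of the secondary wavelet relative to
#'   the primary.
#' @param seed integer seed; all randomness of a simulation call is drawn
#'   from a local generator seeded with it (no global RNG state leaks).
#' @return a validated list of class `SimConfig`.
#' @examples
#' cfg <- simConfig(duration_s = 30, seed = 7)
#' beats <- simulateBeatTimes(cfg)
#' rec <- simulateScg(beats, cfg)
#' @export
simConfig <- function(duration_s = 60, fs = 200, mean_hr_bpm = 70,
                      hr_sd_bpm = 3, rsa_amp_ms = 40, resp_freq_hz = 0.25,
                      jitter_ms = 10,
                      carrier_freq_hz = c(x = 18, y = 14, z = 22),
                      decay_tau_s = c(x = 0.040, y = 0.050, z = 0.035),
                      amplitude = c(x = 0.6, y = 0.8, z = 1.0),
                      noise_snr_db = 10, resp_amp = 0.3, am_depth = 0.2,
                      dual_peak_prob = 0.1, dual_peak_offset_s = 0.15,
                      dual_peak_ratio = 0.5, seed = 1) {
  cfg <- list(
    duration_s = stopIfNot1(duration_s, "duration_s", 0),
    fs = stopIfNot1(fs, "fs", 50),
    mean_hr_bpm = stopIfNot1(mean_hr_bpm, "mean_hr_bpm", 30, 180),
    hr_sd_bpm = stopIfNot1(hr_sd_bpm, "hr_sd_bpm", 0),
    rsa_amp_ms = stopIfNot1(rsa_amp_ms, "rsa_amp_ms", 0),
    resp_freq_hz = stopIfNot1(resp_freq_hz, "resp_freq_hz", 0, 2),
    jitter_ms = stopIfNot1(jitter_ms, "jitter_ms", 0),
    carrier_freq_hz = as.numeric(carrier_freq_hz),
    decay_tau_s = as.numeric(decay_tau_s),
    amplitude = as.numeric(amplitude),
    noise_snr_db = as.numeric(noise_snr_db),
    resp_amp = stopIfNot1(resp_amp, "resp_amp", 0),
    am_depth = stopIfNot1(am_depth, "am_depth", 0, 1),
    dual_peak_prob = stopIfNot1(dual_peak_prob, "dual_peak_prob", 0, 1),
    dual_peak_offset_s = stopIfNot1(dual_peak_offset_s, "dual_peak_offset_s", 0),
    dual_peak_ratio = stopIfNot1(dual_peak_ratio, "dual_peak_ratio", 0),
    seed = as.integer(seed))
  for (nm in c("carrier_freq_hz", "decay_tau_s", "amplitude")) {
    if (length(cfg[[nm]]) != 3L || any(!is.finite(cfg[[nm]])) ||
        any(cfg[[nm]] <= 0))
      stop(sprintf("invalid configuration: '%s' must be 3 positive values", nm),
           call. = FALSE)
  }
  if (length(cfg$noise_snr_db) != 1L || is.na(cfg$noise_snr_db))
    stop("invalid configuration: 'noise_snr_db' must be a single number",
         call. = FALSE)
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate heartbeat times with RSA and slow heart-rate drift
#'
#' Draws a beat-time sequence from the RR-interval model: base RR from a
#' slow mean-reverting Gaussian random walk on heart rate (stationary SD
#' `hr_sd_bpm`, clipped to \[30, 180\] bpm), plus a sinusoidal RSA term of
#' amplitude `rsa_amp_ms` at `resp_freq_hz`, plus white jitter of SD
#' `jitter_ms`. Resulting RR intervals are clipped to the physiological
#' range \[60/180, 60/30\] s. The first beat is at time 0.
#'
#' @param config a [simConfig()] object.
#' @return a [BeatAnnotation-class] with strictly increasing times in
#'   `[0, duration_s)`.
#' @export
simulateBeatTimes <- function(config) {
  if (!inherits(config, "SimConfig")) config <- do.call(simConfig, config)
  if (config$duration_s == 0) return(beatAnnotation(numeric()))
  withLocalSeed(config$seed, {
    rr_min <- 60 / 180; rr_max <- 60 / 30
    # AR(1) on HR with stationary SD hr_sd_bpm, correlation time ~20 beats
    theta <- 0.05
    innov_sd <- config$hr_sd_bpm * sqrt(theta * (2 - theta))
    hr <- config$mean_hr_bpm
    t <- 0; times <- numeric(0)
    while (t < config$duration_s) {
      times <- c(times, t)
      hr <- hr + theta * (config$mean_hr_bpm - hr) + rnorm(1, 0, innov_sd)
      hr <- min(max(hr, 30), 180)
      rr <- 60 / hr +
        config$rsa_amp_ms / 1000 * sin(2 * pi * config$resp_freq_hz * t) +
        rnorm(1, 0, config$jitter_ms / 1000)
      rr <- min(max(rr, rr_min), rr_max)
      t <- t + rr
    }
    beatAnnotation(times)
  })
}

# Superpose one decaying-sinusoid wavelet per (beat, axis) onto `x`.
# tgrid is the uniform sample-time grid; beats/amps vectors per event.
.addWavelets <- function(x, tgrid, beats, amps, f, tau, fs) {
  span <- ceiling(6 * tau * fs)           # truncate at 6 decay constants
  n <- length(x)
  for (j in seq_along(beats)) {
    i0 <- floor((beats[j] - tgrid[1]) * fs) + 1L
    idx <- max(i0, 1L):min(i0 + span, n)
    if (!length(idx) || idx[1] > n) next
    dt <- tgrid[idx] - beats[j]
    keep <- dt >= 0
    idx <- idx[keep]; dt <- dt[keep]
    x[idx] <- x[idx] + amps[j] * exp(-dt / tau) * sin(2 * pi * f * dt)
  }
  x
}

#' Render a tri-axial SCG recording from beat times
#'
#' Each beat contributes one exponentially decaying sinusoid per axis
#' (axis-specific carrier frequency, decay constant and amplitude),
#' amplitude-modulated by respiration; with probability `dual_peak_prob`
#' a second, smaller wavelet follows at `dual_peak_offset_s`. A sub-2-Hz
#' sinusoidal respiration baseline is added per axis, and Gaussian noise
#' scaled so the beat-wavelet component sits at `noise_snr_db` dB above
#' the noise.
#'
#' @param beats a [BeatAnnotation-class]; all times must lie in
#'   `[0, duration_s)`.
#' @param config a [simConfig()] object.
#' @return an [ScgRecording-class] with `round(duration_s * fs)` samples.
#' @export
simulateScg <- function(beats, config) {
  if (!inherits(config, "SimConfig")) config <- do.call(simConfig, config)
  stopifnot(is(beats, "BeatAnnotation"))
  bt <- beatTimes(beats)
  if (length(bt) && (any(bt < 0) || any(bt >= config$duration_s)))
    stop("beat times must lie within [0, duration_s)")
  n <- round(config$duration_s * config$fs)
  if (n < 1L) stop("duration too short for one sample at fs")
  tgrid <- sampleTimes(n, config$fs)
  withLocalSeed(config$seed + 1L, {
    am <- 1 + config$am_depth * sin(2 * pi * config$resp_freq_hz * bt)
    dual <- if (length(bt)) runif(length(bt)) < config$dual_peak_prob
            else logical(0)
    beat_comp <- matrix(0, n, 3)
    for (ax in 1:3) {
      ch <- .addWavelets(numeric(n), tgrid, bt, config$amplitude[ax] * am,
                         config$carrier_freq_hz[ax], config$decay_tau_s[ax],
                         config$fs)
      if (any(dual))
        ch <- .addWavelets(ch, tgrid, bt[dual] + config$dual_peak_offset_s,
                           config$amplitude[ax] * config$dual_peak_ratio *
                             am[dual],
                           config$carrier_freq_hz[ax], config$decay_tau_s[ax],
                           config$fs)
      beat_comp[, ax] <- ch
    }
    phases <- c(0, 2 * pi / 3, 4 * pi / 3)
    resp <- sapply(1:3, function(ax)
      config$resp_amp * config$amplitude[ax] *
        sin(2 * pi * config$resp_freq_hz * tgrid + phases[ax]))
    sig <- beat_comp + resp
    if (is.finite(config$noise_snr_db) && length(bt)) {
      p_beat <- mean(beat_comp^2)
      noise_sd <- sqrt(p_beat * 10^(-config$noise_snr_db / 10))
      sig <- sig + matrix(rnorm(n * 3, 0, noise_sd), n, 3)
    }
    scgRecording(sig, fs = config$fs)
  })
}

#' Motion-artifact configuration
#'
#' @param burst_rate_per_min expected number of motion bursts per minute.
#' @param burst_duration_s duration of each burst in seconds (> 0).
#' @param energy_multiplier target ratio (>= 1) of corrupted-segment to
#'   clean-segment spectral energy, as measured by
#'   [segmentSpectralEnergy()].
#' @param band_hz length-2 frequency band (Hz) of the injected noise.
#' @param seed integer seed for the burst draw.
#' @return a validated list of class `ArtifactConfig`.
#' @export
artifactConfig <- function(burst_rate_per_min = 2, burst_duration_s = 10,
                           energy_multiplier = 20, band_hz = c(2, 25),
                           seed = 1) {
  cfg <- list(
    burst_rate_per_min = stopIfNot1(burst_rate_per_min, "burst_rate_per_min", 0),
    burst_duration_s = stopIfNot1(burst_duration_s, "burst_duration_s", 1e-9),
    energy_multiplier = stopIfNot1(energy_multiplier, "energy_multiplier", 1),
    band_hz = as.numeric(band_hz),
    seed = as.integer(seed))
  if (length(cfg$band_hz) != 2L || cfg$band_hz[1] >= cfg$band_hz[2])
    stop("invalid configuration: 'band_hz' must be (low, high) with low < high",
         call. = FALSE)
  class(cfg) <- "ArtifactConfig"
  cfg
}

#' Inject motion-artifact bursts into a recording
#'
#' Adds band-limited Gaussian noise over randomly placed bursts
#' (Poisson-counted at `burst_rate_per_min`), scaled so that every 10-s
#' analysis segment overlapping a burst has spectral energy (as computed
#' by [segmentSpectralEnergy()]) exceeding `energy_multiplier` times its
#' clean value. Overlapping bursts are merged into disjoint intervals.
#'
#' @param rec an [ScgRecording-class].
#' @param config an [artifactConfig()] object.
#' @param seg_len_s segment length used for energy calibration (default
#'   10 s, matching the artifact detector).
#' @return list with elements `recording` (corrupted copy) and
#'   `intervals` (two-column matrix of disjoint `start_s`, `end_s`).
#' @export
injectMotion <- function(rec, config, seg_len_s = 10) {
  stopifnot(is(rec, "ScgRecording"))
  if (!inherits(config, "ArtifactConfig")) config <- do.call(artifactConfig, config)
  dur <- duration(rec); fs <- samplingRate(rec)
  empty <- matrix(numeric(), 0, 2, dimnames = list(NULL, c("start_s", "end_s")))
  if (config$burst_rate_per_min == 0)
    return(list(recording = rec, intervals = empty))
  withLocalSeed(config$seed, {
    k <- rpois(1, config$burst_rate_per_min * dur / 60)
    if (k == 0) {
      list(recording = rec, intervals = empty)
    } else {
    starts <- sort(runif(k, 0, max(dur - config$burst_duration_s, 0)))
    ints <- cbind(starts, pmin(starts + config$burst_duration_s, dur))
    # merge overlapping draws into disjoint intervals
    merged <- ints[1, , drop = FALSE]
    for (i in seq_len(nrow(ints))[-1]) {
      last <- nrow(merged)
      if (ints[i, 1] <= merged[last, 2])
        merged[last, 2] <- max(merged[last, 2], ints[i, 2])
      else merged <- rbind(merged, ints[i, ])
    }
    colnames(merged) <- c("start_s", "end_s")
    clean_E <- segmentSpectralEnergy(rec, seg_len_s = seg_len_s,
                                     band_hz = config$band_hz)
    sig <- scgSignal(rec)
    n <- nrow(sig)
    bp <- signal::butter(4, config$band_hz / (fs / 2), type = "pass")
    for (i in seq_len(nrow(merged))) {
      i0 <- floor(merged[i, 1] * fs) + 1L
      i1 <- min(ceiling(merged[i, 2] * fs), n)
      len <- i1 - i0 + 1L
      noise <- sapply(1:3, function(ax)
        as.numeric(signal::filter(bp, rnorm(len))))
      noise <- matrix(noise, len, 3)
      # scale so each overlapped segment clears the multiplier with margin
      probe <- matrix(0, n, 3); probe[i0:i1, ] <- noise
      noise_E <- segmentSpectralEnergy(
        scgRecording(probe, fs = fs, t0 = timeOrigin(rec)),
        seg_len_s = seg_len_s, band_hz = config$band_hz)
      segs <- attr(clean_E, "bounds")
      hit <- which(segs[, 1] < merged[i, 2] & segs[, 2] > merged[i, 1] &
                   noise_E > 0)
      if (!length(hit)) next
      s2 <- 2 * config$energy_multiplier *
        max(clean_E[hit] / noise_E[hit])
      sig[i0:i1, ] <- sig[i0:i1, ] + sqrt(s2) * noise
    }
    list(recording = scgRecording(sig, fs = fs, t0 = timeOrigin(rec),
                                  channelNames = rec@channelNames),
         intervals = merged)
    }
  })
}
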