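---
title: "Heartbeat detection from tri-axial seismocardiography: models and methods"
author: "scgbeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heartbeat detection from tri-axial seismocardiography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Seismocardiography (SCG) records the micro-vibrations of the chest wall
produced by the beating heart with a tri-axial accelerometer worn on the
thorax. Each heartbeat appears as a short burst of oscillation, roughly
in the 10--25 Hz band, riding on low-frequency respiratory motion and
broadband sensor noise, with substantial inter-subject variability in
waveform shape. `scgbeat` implements a complete pipeline that turns such
recordings into beat times and windowed heart-rate (HR) estimates:

1. preprocessing (resampling to 200 Hz, zero-phase high-pass at 2 Hz,
   robust median-based amplitude scaling);
2. per-sample heartbeat masks built from reference RR intervals;
3. a 1D encoder--decoder segmentation network producing per-sample
   heartbeat probabilities from the three channels jointly;
4. rule-based localization of discrete beats in the probability mask;
5. inter-beat-interval (IBI) correction and quality-gated sliding-window
   HR estimation;
6. spectral-energy flagging of movement-corrupted segments;
7. tolerance-based detection scoring and Bland--Altman HR agreement.

Because clinical SCG corpora are rarely redistributable, the package
ships a seeded synthetic simulator that generates tri-axial recordings
with known beat times, so that every stage is exercised end to end by
code alone.

## The synthetic signal model

`simConfig()` fixes the generative model.

*RR process.* Heart rate follows a slow mean-reverting Gaussian walk
(AR(1) with stationary SD `hr_sd_bpm`, default 3 bpm, correlation time
about 20 beats) around `mean_hr_bpm` (default 70 bpm, clipped to
30--180 bpm). Each interval adds a respiratory sinus arrhythmia term,
`rsa_amp_ms` (40 ms) times a sinusoid at the respiration frequency
(0.25 Hz), and white jitter (`jitter_ms`, 10 ms). Intervals are clipped
to the physiological range [60/180, 60/30] s.

*Waveform.* Each beat contributes one exponentially decaying sinusoid
per axis. Carriers (18, 14, 22 Hz), decay constants (40, 50, 35 ms) and
amplitudes (0.6, 0.8, 1.0) differ per axis, matching the band that the
SCG literature attributes to cardiomechanical vibration and giving the
network a reason to use all three channels. With probability
`dual_peak_prob` (0.1) a beat carries a second wavelet at +150 ms with
half amplitude, emulating the dual-acceleration morphology seen in a
minority of subjects. Respiration enters twice: as an additive sub-2-Hz
baseline (`resp_amp`, 0.3 relative units) and as a multiplicative
amplitude modulation of the wavelets (`am_depth`, 0.2). Gaussian noise
is scaled so the beat-wavelet component sits at `noise_snr_db` (10 dB)
above it; the calibration is exact by construction and verified
empirically to within 1 dB in the tests.

These defaults are stated assumptions, chosen once as plausible for
chest-worn resting recordings; no public reference distribution exists
to calibrate them against. What the simulator deliberately does *not*
emulate: real waveform variability across subjects and postures,
arrhythmia beyond RR jitter, sensor drift, and any coupling between
motion artifacts and beat morphology. Passing the recovery tests
therefore demonstrates that the pipeline's machinery is correct and
self-consistent, not that its accuracy transfers to clinical data.

*Motion bursts.* `injectMotion()` adds band-limited (2--25 Hz) Gaussian
noise over Poisson-placed bursts, scaled per overlapped 10-s analysis
segment so the segment's spectral energy exceeds `energy_multiplier`
times its clean value (with a factor-2 margin), and merges overlapping
draws into disjoint intervals. All simulator randomness is drawn from a
local generator seeded per call; the caller's RNG state is untouched.

## Preprocessing choices

The high-pass is a Butterworth design (the filter family is a package
choice) of order 4 with a 2 Hz cutoff, applied forward and backward so
that events keep their timing; the doubled effective attenuation of the
two-pass application is accepted. Edge handling uses odd-reflection
padding of three cutoff periods (`3 * fs / cutoff` samples), long
enough to absorb the filter transient; residual edge effects decay
within roughly two seconds of either end, and the idempotence property
(refiltering changes nothing) holds to ~1e-6 relative RMS in the
steady-state region.

Resampling interpolates linearly onto the uniform target grid; when
downsampling, a 4th-order zero-phase low-pass at 0.45 x target rate
guards against aliasing. Upsampling is not anti-alias filtered.

Median scaling partitions each channel into 4096-sample windows (a
final partial window counts if at least half length), takes the median
of window minima `m` and of window maxima `M`, maps `[m, M]` affinely
to `[-1, 1]`, and clips to `[-1.5, 1.5]` — stable global bounds that a
single spiky window cannot corrupt, with mild overshoot preserved and
gross outliers capped. Scaling is per channel (axes have genuinely
different gains); a flat channel maps to zero with a warning rather
than aborting batch work. Gap validation for non-uniformly delivered
wrist data splits the timestamp sequence into maximal runs whose
internal gaps are at most 0.05 s.

## Masks and the segmentation network

Ground-truth masks mark every sample within 0.1 s of a beat, i.e. a
0.2 s window per beat. The 0.1 s figure is read as a *half*-width: the
detector's 160-sample minimum width at 1000 Hz is documented as 80% of
the reference mask width, which forces a 200-sample (0.2 s) reference
window. Overlapping windows merge by logical OR. The temporal anchor
between an external RR stream and the SCG clock is an explicit
parameter (`anchorS`); the simulator provides exact anchors.

The network is a 1D U-Net: five encoder stages of two
(convolution - batch norm - ReLU) blocks with kernel length 30,
16 filters initially and doubling per stage, max-pooling (stride 2)
between stages; a two-block bridge; a mirrored decoder using
transposed convolutions (kernel 2, stride 2) and skip concatenation;
and a per-sample linear head with softmax over the two classes
(heartbeat / background). The head is per-sample — a kernel-1
convolution — which is the only shape-consistent reading of a "fully
connected" output layer for variable-length inputs. Convolutions use
same-padding so encoder and decoder lengths match for concatenation.

Training minimizes class-weighted cross-entropy (weights default to
inverse class frequency computed from the training masks, normalized
to mean 1) with Adam at an initial rate of 1e-3, batch 128. When
validation loss fails to improve for two consecutive epochs the rate
drops tenfold, and training stops once the schedule would fall below
1e-6 while validation loss still stalls; the best-validation weights
are kept. "Improvement" is compared without a tolerance.

The engine behind `buildUNet()`/`trainUNet()` is a compact CPU
implementation written for this package: single-precision im2col + GEMM
convolutions, batch normalization with running statistics, max-pooling
with stored argmax, transposed-convolution upsampling, and Adam, all
driven deterministically from user seeds, so identical seeds reproduce
identical training trajectories bit for bit on a fixed BLAS.

Whole-recording inference tiles the signal into 4096-sample windows at
50% overlap (tail window right-aligned, short recordings
reflect-padded and cropped) and averages the heartbeat-class
probability over overlapping windows.

*Problem sizes.* The package's end-to-end checks train the full
architecture (depth 5, 16 initial filters, kernel 30, 4096-sample
segments) on 300 simulated segments (280 train / 20 validation) with
batch 4 for two epochs, then score 50 held-out segments. Small batches
at few epochs maximize optimizer steps for a fixed number of
convolution evaluations; on this simulator the task converges well
within that budget (interior beats are recovered perfectly after the
first epoch, and the residual misses sit at segment edges where the
mask window is truncated). The batch-128 default and the full learning
rate schedule remain available for larger runs.

## Beat localization

The probability mask is linearly interpolated to 1000 Hz, binarized at
a strict 0.8 threshold (a plateau exactly at the threshold is
excluded), maximal supra-threshold runs narrower than 160 samples are
discarded, and a minimum separation of 0.55 s is enforced between the
surviving runs' centres. When two runs conflict, the one with the
higher mean probability survives (ties to the earlier run) and the
scan re-checks leftwards — the rule is deterministic and
order-independent in the physiological regime. Beat time is the
unweighted mean sample index of the run.

Two numerical notes. First, a beat whose time falls between 200 Hz
samples has its mask run centre quantized to half an input sample, so
round trips through 200 Hz ground-truth masks are exact only to
~2.5 ms (plus at most one 1 ms interpolation sample); at the 1000 Hz
mask grid the bound is 0.5 ms. Second, threshold monotonicity (raising
the threshold never yields more beats) holds for unimodal, beat-like
confidence bumps — the regime the rule set targets — but not for
arbitrary masks, where a merged plateau can split into two widely
separated runs; the property test generates the former.

## Heart rate with quality gating

Beat-to-beat intervals are corrected by a running-median /
quartile-deviation procedure that runs in phases, re-estimating its
statistics after each phase so a repaired stretch no longer biases the
next decision: (1) adjacent short pairs whose sum is plausible merge
(extra beat); (2) intervals near an integer multiple of the local
median split into equal parts (missed beats); (3) long/short adjacent
pairs with a plausible mean are redistributed (misaligned beat);
(4) whatever still deviates is excluded. The flagging threshold is
`min(max(3 * QD, 0.03 s), 0.3 * median)` — the quartile-deviation term
adapts to the series' own variability, the floor avoids flagging clean
metronomic data, and the ceiling keeps gross corruption detectable even
when it inflates the QD. Every correction conserves the spanned time
exactly. This corrector is a deliberately simple, fully documented
quality procedure; the proprietary signal-quality classifier used in
the original acquisition software is out of scope, and its role
(excluding untrustworthy stretches) is covered by the `excluded` flag
plus `excludeArtifactIbi()`, which excludes intervals overlapping
flagged motion segments.

HR is computed in 20 s windows (step = window by default; the window
grid origin is configurable so that independently detected series can
be compared window for window). Within a window, the *effective
length* is the summed duration of `good` intervals — corrected and
excluded intervals do not count — lying fully inside, divided by the
window length. HR = 60 / mean(IBI in seconds) over those intervals,
reported only when the effective fraction strictly exceeds 0.5.
Defined values are bounded in (20, 240) bpm by interval validation.

## Movement-artifact flagging

Recordings are divided into 10 s segments (a partial tail is dropped);
per segment the spectral energy is the sum over channels and STFT
frames of squared magnitudes in the 2--25 Hz band, using a 1 s Hann
window at 50% overlap. A segment is flagged when its energy strictly
exceeds five times the recording's minimum segment energy. The STFT
parameters and band are package choices (the band matches the
high-pass cutoff below and the cardiomechanical band above) and are
configurable; the band is half-open at the low edge so that content at
exactly the cutoff — already in the high-pass stop band — does not
count. Self-normalization needs at least two segments; shorter
recordings yield no flags, with a warning. The flags are scale
invariant by construction.

## Evaluation

Detection is scored by chronological greedy matching: each prediction
pairs with the nearest unmatched reference within 0.1 s (inclusive;
ties to the earlier reference). For references separated by more than
twice the tolerance — guaranteed for valid physiological series, since
0.55 s > 0.2 s — greedy matching attains maximum cardinality, which the
tests verify against an exhaustive matcher. PPV, sensitivity and F1
report `NA` on empty denominators rather than a forced 0. HR agreement
pairs the two series on common defined windows and reports MAE, RMSE,
Pearson r (undefined on zero variance), Bland--Altman bias, 1.96 SD
limits of agreement, and the SD of differences (SEE). Evaluation can
exclude beats and intervals inside flagged segments to mirror an
artifact-free protocol.

## Known limitations

* Synthetic-to-real transfer is untested by design; the simulator's
  defaults are assumptions, not fits to a clinical corpus.
* The corrector approximates, but does not reproduce, published
  beat-classification algorithms; its thresholds are heuristic.
* Greedy matching is only provably optimal when reference spacing
  exceeds twice the tolerance.
* Bit-exact training reproducibility assumes a fixed single-threaded
  BLAS; different BLAS builds may change results at floating-point
  level.
* WFDB-format interchange is not implemented; recordings, beats, RR
  streams, masks and flags travel as documented columnar text.
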