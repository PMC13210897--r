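#' Pipeline configuration
#'
#' Aggregates all stage parameters with the published defaults: 2 Hz
#' 4th-order zero-phase high-pass, 200 Hz target rate, 4096-sample
#' scaling and training segments, U-Net depth 5 / 16 initial filters /
#' kernel 30, batch 128 with learning rate 1e-3 down to 1e-6, 1000 Hz
#' detection grid with 0.8 threshold / 160-sample minimum width /
#' 0.55 s separation, 20 s HR windows gated at 50% effective length,
#' 0.1 s matching tolerance, and 10 s artifact segments flagged above
#' 5x the minimum spectral energy. The `scale` section sets the demo
#' problem sizes (number of segments, recordings, epochs).
#'
#' @param sim named list overriding [simConfig()] defaults.
#' @param preprocess named list overriding [preprocessParams()] defaults.
#' @param model named list overriding [unetConfig()] defaults.
#' @param train named list overriding [trainConfig()] defaults.
#' @param detect named list overriding [detectionParams()] defaults.
#' @param hr named list: `window_s` (20), `step_s` (20),
#'   `min_effective` (0.5).
#' @param artifacts named list: `seg_len_s` (10), `band_hz` (c(2, 25)),
#'   `ratio_threshold` (5).
#' @param evaluate named list: `tolerance_s` (0.1).
#' @param scale named list: `n_train`, `n_val`, `n_test`,
#'   `test_duration_s`.
#' @param seed global seed; stage seeds are derived from it.
#' @param out_dir output directory.
#' @return a validated nested list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(sim = list(), preprocess = list(),
                           model = list(), train = list(),
                           detect = list(), hr = list(),
                           artifacts = list(), evaluate = list(),
                           scale = list(), seed = 1,
                           out_dir = "scgbeat_out") {
  merge <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad))
      stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    defaults[names(user)] <- user
    defaults
  }
  hr_d <- merge(list(window_s = 20, step_s = 20, min_effective = 0.5), hr)
  art_d <- merge(list(seg_len_s = 10, band_hz = c(2, 25),
                      ratio_threshold = 5), artifacts)
  ev_d <- merge(list(tolerance_s = 0.1), evaluate)
  sc_d <- merge(list(n_train = 40, n_val = 10, n_test = 3,
                     test_duration_s = 60), scale)
  cfg <- list(sim = sim, preprocess = preprocess, model = model,
              train = train, detect = detect, hr = hr_d,
              artifacts = art_d, evaluate = ev_d, scale = sc_d,
              seed = as.integer(seed), out_dir = out_dir)
  # force full validation of every section now, not at run time
  do.call(simConfig, cfg$sim)
  pp <- do.call(preprocessParams, cfg$preprocess)
  do.call(unetConfig, cfg$model)
  do.call(trainConfig, cfg$train)
  do.call(detectionParams, cfg$detect)
  if (pp$hp_cutoff_hz >= pp$target_fs / 2)
    stop("hp_cutoff_hz must be below target_fs / 2", call. = FALSE)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with (optional) sections named as in
#'   [pipelineConfig()].
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  do.call(pipelineConfig, y)
}

#' Simulate a batch of training segments
#'
#' Draws `n` independent synthetic recordings (one derived seed each),
#' preprocesses them (high-pass + median scaling), crops the first
#' `input_len` samples and rasterizes the known beat times into binary
#' target masks.
#'
#' @param n number of segments.
#' @param config a [simConfig()]; its duration is overridden to cover
#'   `input_len` samples.
#' @param pp a [preprocessParams()].
#' @param input_len segment length in samples (default 4096).
#' @param seed base seed; segment `i` uses `seed + i`.
#' @return a [segmentBatch()] with an attached list of per-segment
#'   [BeatAnnotation-class] objects (attribute `"beats"`).
#' @export
simulateSegmentBatch <- function(n, config = simConfig(),
                                 pp = preprocessParams(),
                                 input_len = 4096, seed = 1) {
  fs <- config$fs
  dur <- ceiling(input_len / fs) + 1
  inputs <- array(0, dim = c(3, input_len, n))
  targets <- matrix(0L, input_len, n)
  beats_list <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$duration_s <- dur
    cfg_i$seed <- as.integer(seed + i)
    beats <- simulateBeatTimes(cfg_i)
    rec <- simulateScg(beats, cfg_i)
    rec <- medianScale(highpassRecording(rec, pp), pp)
    sig <- scgSignal(rec)[seq_len(input_len), , drop = FALSE]
    t_max <- input_len / fs
    bt <- beatTimes(beats)
    bt <- bt[bt < t_max - 1 / fs]
    mask <- beatsToMask(beatAnnotation(bt), fs = fs, length = input_len)
    inputs[, , i] <- t(sig)
    targets[, i] <- as.integer(maskValues(mask))
    beats_list[[i]] <- beatAnnotation(bt)
  }
  out <- segmentBatch(inputs, targets)
  attr(out, "beats") <- beats_list
  out
}

#' Run the pipeline end to end on synthetic data
#'
#' Stages: `simulate` (test recordings + reference beats),
#' `preprocess`, `train` (segments are generated from the same
#' configuration), `detect`, `hr`, `artifacts`, `evaluate`. Each stage
#' writes its outputs under `out_dir` and a `manifest.json` (config
#' hash, seed, package version) for reproducibility; stages other than
#' `all` expect the upstream stage's files to exist.
#'
#' @param config a [pipelineConfig()].
#' @param stage one of `all`, `simulate`, `preprocess`, `train`,
#'   `detect`, `hr`, `artifacts`, `evaluate`.
#' @param verbose print stage progress.
#' @return (invisibly) a list with the evaluation metrics (when run),
#'   per-stage file paths, and the manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), stage = "all",
                        verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- match.arg(stage, c("all", "simulate", "preprocess", "train",
                              "detect", "hr", "artifacts", "evaluate"))
  out <- config$out_dir
  dirs <- file.path(out, c("sim", "prep", "train", "detect", "hr",
                           "artifacts", "evaluate"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  pp <- do.call(preprocessParams, config$preprocess)
  simc <- do.call(simConfig, config$sim)
  ucfg <- do.call(unetConfig, config$model)
  dp <- do.call(detectionParams, config$detect)
  n_test <- config$scale$n_test
  say <- function(...) if (verbose) message(sprintf(...))

  manifest <- list(config_hash = .configHash(config), seed = config$seed,
                   package = "scgbeat",
                   version = as.character(utils::packageVersion("scgbeat")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  recf <- function(i) file.path(out, "sim", sprintf("test_rec_%02d.tsv", i))
  beatf <- function(i) file.path(out, "sim", sprintf("test_beats_%02d.txt", i))
  prepf <- function(i) file.path(out, "prep", sprintf("test_rec_%02d.tsv", i))
  predf <- function(i) file.path(out, "detect", sprintf("pred_beats_%02d.txt", i))
  modelf <- file.path(out, "train", "model.json")

  need <- function(path, from) {
    if (!file.exists(path))
      stop(sprintf("missing upstream artifact '%s': run stage '%s' first",
                   path, from), call. = FALSE)
    path
  }

  if (stage %in% c("all", "simulate")) {
    say("simulate: %d test recordings of %g s", n_test,
        config$scale$test_duration_s)
    for (i in seq_len(n_test)) {
      cfg_i <- simc
      cfg_i$duration_s <- config$scale$test_duration_s
      cfg_i$seed <- config$seed * 1000L + i
      beats <- simulateBeatTimes(cfg_i)
      writeRecording(simulateScg(beats, cfg_i), recf(i))
      writeBeats(beats, beatf(i))
    }
  }
  if (stage %in% c("all", "preprocess")) {
    for (i in seq_len(n_test)) {
      rec <- readRecording(need(recf(i), "simulate"))
      rec <- resampleRecording(rec, pp$target_fs)
      writeRecording(medianScale(highpassRecording(rec, pp), pp), prepf(i))
    }
  }
  model <- NULL
  if (stage %in% c("all", "train")) {
    say("train: %d + %d segments", config$scale$n_train, config$scale$n_val)
    tr <- simulateSegmentBatch(config$scale$n_train, simc, pp,
                               ucfg$input_len, seed = config$seed * 10000L)
    va <- simulateSegmentBatch(config$scale$n_val, simc, pp,
                               ucfg$input_len,
                               seed = config$seed * 10000L + 5000L)
    tc <- do.call(trainConfig, config$train)
    model <- trainUNet(buildUNet(ucfg, seed = config$seed), tr, va, tc,
                       verbose = verbose)
    saveUNet(model, modelf)
    hist <- attr(model, "history")
    write.table(hist, file.path(out, "train", "history.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
  }
  if (stage %in% c("all", "detect")) {
    if (is.null(model)) model <- loadUNet(need(modelf, "train"))
    for (i in seq_len(n_test)) {
      rec <- readRecording(need(prepf(i), "preprocess"))
      prob <- predictProba(model, rec)
      writeBeats(localizeBeats(prob, dp), predf(i))
    }
  }
  if (stage %in% c("all", "hr")) {
    for (i in seq_len(n_test)) {
      est <- correctIbi(beatsToIbi(readBeats(need(predf(i), "detect"))))
      writeHr(estimateHr(est, config$hr$window_s, config$hr$step_s,
                         config$hr$min_effective),
              file.path(out, "hr", sprintf("hr_%02d.csv", i)))
      ref <- beatsToIbi(readBeats(need(beatf(i), "simulate")))
      writeHr(estimateHr(ref, config$hr$window_s, config$hr$step_s,
                         config$hr$min_effective),
              file.path(out, "hr", sprintf("ref_hr_%02d.csv", i)))
    }
  }
  if (stage %in% c("all", "artifacts")) {
    for (i in seq_len(n_test)) {
      rec <- readRecording(need(prepf(i), "preprocess"))
      e <- segmentSpectralEnergy(rec, config$artifacts$seg_len_s,
                                 config$artifacts$band_hz)
      writeArtifactFlags(flagArtifacts(e, config$artifacts$ratio_threshold),
                         file.path(out, "artifacts",
                                   sprintf("flags_%02d.tsv", i)))
    }
  }
  metrics <- NULL
  if (stage %in% c("all", "evaluate")) {
    tp <- fp <- fn <- 0L
    est_all <- ref_all <- list()
    for (i in seq_len(n_test)) {
      m <- matchBeats(readBeats(need(predf(i), "detect")),
                      readBeats(need(beatf(i), "simulate")),
                      config$evaluate$tolerance_s)
      tp <- tp + m@tp; fp <- fp + m@fp; fn <- fn + m@fn
      est_i <- readHr(need(file.path(out, "hr", sprintf("hr_%02d.csv", i)),
                           "hr"))
      ref_i <- readHr(file.path(out, "hr", sprintf("ref_hr_%02d.csv", i)))
      # offset window centres per recording so series never collide
      off <- i * 10 * config$scale$test_duration_s
      est_all[[i]] <- hrSeries(windowCenters(est_i) + off, hrValues(est_i),
                               effectiveFraction(est_i))
      ref_all[[i]] <- hrSeries(windowCenters(ref_i) + off, hrValues(ref_i),
                               effectiveFraction(ref_i))
    }
    est <- hrSeries(unlist(lapply(est_all, windowCenters)),
                    unlist(lapply(est_all, hrValues)),
                    unlist(lapply(est_all, effectiveFraction)))
    ref <- hrSeries(unlist(lapply(ref_all, windowCenters)),
                    unlist(lapply(ref_all, hrValues)),
                    unlist(lapply(ref_all, effectiveFraction)))
    agree <- hrAgreement(est, ref)
    ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(ppv) && !is.na(sens) && ppv + sens > 0)
      2 * ppv * sens / (ppv + sens) else NA_real_
    metrics <- list(tp = tp, fp = fp, fn = fn, ppv = ppv,
                    sensitivity = sens, f1 = f1,
                    hr = unclass(agree))
    jsonlite::write_json(metrics, file.path(out, "evaluate", "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(metrics = metrics, out_dir = out, manifest = manifest))
}

# Stable hash of a configuration (md5 of its canonical JSON form); the
# output directory is not part of the analysis identity.
.configHash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
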