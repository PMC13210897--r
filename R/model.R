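#' 1D U-Net architecture configuration
#'
#' The segmentation network maps 3-channel SCG segments to per-sample
#' 2-class (heartbeat / non-heartbeat) probabilities. The encoder has
#' `depth` stages of two convolution--batch-norm--ReLU blocks with
#' max-pooling (stride 2); filters double per stage from `init_filters`;
#' a two-block bridge joins the mirrored decoder, which upsamples with
#' transposed convolutions and concatenates the encoder skip features.
#' The head is a per-sample linear map followed by a softmax.
#'
#' @param depth number of encoder stages (default 5).
#' @param init_filters filters in the first encoder stage (default 16).
#' @param kernel_size convolution kernel length in samples (default 30).
#' @param in_channels input channels (default 3).
#' @param classes output classes (default 2).
#' @param input_len training segment length in samples (default 4096);
#'   must be divisible by `2^depth`.
#' @return a validated list of class `UNetConfig`.
#' @export
unetConfig <- function(depth = 5, init_filters = 16, kernel_size = 30,
                       in_channels = 3, classes = 2, input_len = 4096) {
  cfg <- list(depth = as.integer(stopIfNot1(depth, "depth", 1)),
              init_filters = as.integer(stopIfNot1(init_filters,
                                                   "init_filters", 1)),
              kernel_size = as.integer(stopIfNot1(kernel_size,
                                                  "kernel_size", 1)),
              in_channels = as.integer(stopIfNot1(in_channels,
                                                  "in_channels", 1)),
              classes = as.integer(stopIfNot1(classes, "classes", 2)),
              input_len = as.integer(stopIfNot1(input_len, "input_len", 2)))
  if (cfg$input_len %% 2^cfg$depth != 0)
    stop("invalid configuration: 'input_len' must be divisible by 2^depth",
         call. = FALSE)
  class(cfg) <- "UNetConfig"
  cfg
}

#' Training configuration
#'
#' @param batch_size segments per optimizer step (default 128).
#' @param lr_init initial Adam learning rate (default 1e-3).
#' @param lr_factor multiplier applied when validation loss stalls
#'   (default 0.1).
#' @param lr_patience_epochs epochs without validation improvement
#'   before the learning rate is reduced (default 2).
#' @param lr_min training stops once the schedule would drop below this
#'   rate and validation loss still fails to improve (default 1e-6).
#' @param class_weights per-class loss multipliers; `NULL` (default)
#'   computes inverse class frequencies from the training masks,
#'   normalized to mean 1.
#' @param max_epochs upper bound on epochs (default 50).
#' @param seed integer seed for weight initialization and shuffling.
#' @return a validated list of class `TrainConfig`.
#' @export
trainConfig <- function(batch_size = 128, lr_init = 1e-3, lr_factor = 0.1,
                        lr_patience_epochs = 2, lr_min = 1e-6,
                        class_weights = NULL, max_epochs = 50, seed = 1) {
  cfg <- list(batch_size = as.integer(stopIfNot1(batch_size, "batch_size", 1)),
              lr_init = stopIfNot1(lr_init, "lr_init", 1e-12),
              lr_factor = stopIfNot1(lr_factor, "lr_factor", 1e-12, 1),
              lr_patience_epochs = as.integer(stopIfNot1(lr_patience_epochs,
                                                         "lr_patience_epochs", 1)),
              lr_min = stopIfNot1(lr_min, "lr_min", 0),
              class_weights = class_weights,
              max_epochs = as.integer(stopIfNot1(max_epochs, "max_epochs", 1)),
              seed = as.integer(seed))
  if (cfg$lr_min > cfg$lr_init)
    stop("invalid configuration: 'lr_min' must not exceed 'lr_init'",
         call. = FALSE)
  class(cfg) <- "TrainConfig"
  cfg
}

#' UNetModel: a segmentation network instance
#'
#' Wraps the compiled network engine. The full state (weights plus
#' batch-norm statistics) is mirrored in the `state` slot so models can
#' be serialized and restored; the engine pointer is rebuilt on demand.
#'
#' @slot config a [unetConfig()] list.
#' @slot state numeric vector of all weights and batch-norm statistics.
#' @slot env environment caching the engine pointer.
#' @exportClass UNetModel
setClass("UNetModel",
  representation(config = "list", state = "numeric", env = "environment"))

#' Build an untrained segmentation network
#'
#' @param config a [unetConfig()] object.
#' @param seed integer seed for He-normal weight initialization.
#' @return a [UNetModel-class].
#' @export
buildUNet <- function(config = unetConfig(), seed = 1) {
  if (!inherits(config, "UNetConfig")) config <- do.call(unetConfig, config)
  env <- new.env(parent = emptyenv())
  env$ptr <- unet_create(config$depth, config$init_filters,
                         config$kernel_size, config$in_channels,
                         config$classes, as.integer(seed))
  new("UNetModel", config = unclass(config),
      state = unet_get_state(env$ptr), env = env)
}

# Engine pointer for a model, rebuilding it (and restoring the state)
# after deserialization.
.modelPtr <- function(model) {
  env <- model@env
  if (is.null(env$ptr) || !unet_ptr_valid(env$ptr)) {
    cfg <- model@config
    env$ptr <- unet_create(cfg$depth, cfg$init_filters, cfg$kernel_size,
                           cfg$in_channels, cfg$classes, 1L)
    unet_set_state(env$ptr, model@state)
  }
  env$ptr
}

#' Number of trainable parameters of a model
#'
#' @param model a [UNetModel-class].
#' @return parameter count (weights, biases, batch-norm scale/shift;
#'   running statistics excluded).
#' @export
unetParamCount <- function(model) {
  stopifnot(is(model, "UNetModel"))
  unet_param_count(.modelPtr(model))
}

setMethod("show", "UNetModel", function(object) {
  cfg <- object@config
  cat(sprintf("UNetModel: depth %d, %d initial filters, kernel %d, %d -> %d channels\n",
              cfg$depth, cfg$init_filters, cfg$kernel_size,
              cfg$in_channels, cfg$classes))
  cat(sprintf("  %d trainable parameters\n", unetParamCount(object)))
})

#' Assemble a segment batch
#'
#' @param inputs numeric array `(channels, input_len, n)` of scaled SCG
#'   segments.
#' @param targets numeric or integer matrix `(input_len, n)` of binary
#'   masks.
#' @return a list of class `SegmentBatch`.
#' @export
segmentBatch <- function(inputs, targets) {
  stopifnot(length(dim(inputs)) == 3L, length(dim(targets)) == 2L,
            dim(inputs)[2] == nrow(targets), dim(inputs)[3] == ncol(targets))
  if (any(!targets %in% c(0, 1))) stop("targets must be binary")
  structure(list(inputs = inputs, targets = targets), class = "SegmentBatch")
}

# (channels, L, k) array slice -> (channels, k*L) engine layout
.flattenBatch <- function(inputs, idx) {
  matrix(inputs[, , idx, drop = FALSE], nrow = dim(inputs)[1])
}

#' Train a segmentation network
#'
#' Minimizes class-weighted cross-entropy with Adam. After each epoch
#' the validation loss (batch-norm in inference mode) is evaluated; when
#' it fails to improve for `lr_patience_epochs` consecutive epochs the
#' learning rate is multiplied by `lr_factor`, and training stops when
#' the schedule would fall below `lr_min` while validation loss still
#' fails to improve (or at `max_epochs`). The weights with the best
#' validation loss are returned.
#'
#' @param model a [UNetModel-class] from [buildUNet()].
#' @param train,val `SegmentBatch` objects (see [segmentBatch()]).
#' @param tc a [trainConfig()] object.
#' @param verbose print per-epoch progress.
#' @return the trained [UNetModel-class]; the training history (a
#'   data.frame with epoch, train_loss, val_loss, lr) is attached as
#'   attribute `"history"`.
#' @export
trainUNet <- function(model, train, val, tc = trainConfig(),
                      verbose = FALSE) {
  stopifnot(is(model, "UNetModel"), inherits(train, "SegmentBatch"),
            inherits(val, "SegmentBatch"))
  n_train <- dim(train$inputs)[3]
  n_val <- dim(val$inputs)[3]
  if (n_train < 1L || n_val < 1L) stop("empty segment stream")
  ptr <- .modelPtr(model)
  w <- tc$class_weights
  if (is.null(w)) {
    freq <- c(mean(train$targets == 0), mean(train$targets == 1))
    freq <- pmax(freq, 1e-6)
    w <- (1 / freq) / mean(1 / freq)
  }
  val_x <- .flattenBatch(val$inputs, seq_len(n_val))
  val_y <- as.integer(val$targets)
  lr <- tc$lr_init
  best_val <- Inf; best_state <- unet_get_state(ptr)
  stall <- 0L
  hist <- list()
  withLocalSeed(tc$seed, {
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample.int(n_train)
      losses <- numeric(0)
      for (b0 in seq(1L, n_train, by = tc$batch_size)) {
        idx <- ord[b0:min(b0 + tc$batch_size - 1L, n_train)]
        x <- .flattenBatch(train$inputs, idx)
        y <- as.integer(train$targets[, idx])
        lo <- unet_train_batch(ptr, x, y, w, length(idx), lr)
        if (!is.finite(lo))
          stop(sprintf("training diverged: non-finite loss at epoch %d", epoch))
        losses <- c(losses, lo)
      }
      val_loss <- unet_eval_loss(ptr, val_x, val_y, w, n_val)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = mean(losses),
                                  val_loss = val_loss, lr = lr)
      if (verbose)
        message(sprintf("epoch %d: train %.4f, val %.4f, lr %.1e",
                        epoch, mean(losses), val_loss, lr))
      if (val_loss < best_val) {
        best_val <- val_loss
        best_state <- unet_get_state(ptr)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tc$lr_patience_epochs) {
          if (lr * tc$lr_factor < tc$lr_min) break
          lr <- lr * tc$lr_factor
          stall <- 0L
        }
      }
    }
  })
  unet_set_state(ptr, best_state)
  out <- new("UNetModel", config = model@config, state = best_state,
             env = model@env)
  attr(out, "history") <- do.call(rbind, hist)
  out
}

#' Per-sample heartbeat probabilities for a whole recording
#'
#' Tiles the recording into `input_len`-sample windows with 50% overlap
#' (the tail window is right-aligned; recordings shorter than one window
#' are reflect-padded and cropped) and averages the heartbeat-class
#' probability over overlapping windows.
#'
#' @param model a trained [UNetModel-class].
#' @param rec an [ScgRecording-class], preprocessed (high-passed and
#'   median-scaled) at the rate the model was trained on.
#' @return a [SampleMask-class] of heartbeat probabilities, same length
#'   and timeline as `rec`.
#' @export
predictProba <- function(model, rec) {
  stopifnot(is(model, "UNetModel"), is(rec, "ScgRecording"))
  n <- nSamples(rec)
  if (n < 2L) stop("recording too short for inference")
  L <- model@config$input_len
  sig <- t(scgSignal(rec))                     # (channels, n)
  pad <- 0L
  if (n < L) {
    pad <- L - n
    refl <- sig[, rev(seq_len(min(pad, n - 1L))), drop = FALSE]
    while (ncol(refl) < pad)                   # very short recordings
      refl <- cbind(refl, refl[, ncol(refl)])
    sig <- cbind(sig, refl)
  }
  total <- ncol(sig)
  offs <- unique(c(seq(0L, total - L, by = L %/% 2L), total - L))
  ptr <- .modelPtr(model)
  acc <- numeric(total); cnt <- numeric(total)
  for (o in offs) {
    x <- sig[, (o + 1L):(o + L), drop = FALSE]
    p <- unet_forward(ptr, x, 1L, FALSE)
    acc[(o + 1L):(o + L)] <- acc[(o + 1L):(o + L)] + p[2L, ]
    cnt[(o + 1L):(o + L)] <- cnt[(o + 1L):(o + L)] + 1
  }
  sampleMask(pmin(pmax(acc[seq_len(n)] / cnt[seq_len(n)], 0), 1),
             fs = samplingRate(rec), t0 = timeOrigin(rec))
}

#' Per-sample class probabilities for a raw segment batch
#'
#' Low-level forward pass used by tests and training diagnostics.
#'
#' @param model a [UNetModel-class].
#' @param batch a `SegmentBatch` or `(channels, L, n)` array.
#' @return numeric array `(classes, L, n)` of per-sample probabilities.
#' @export
forwardUNet <- function(model, batch) {
  stopifnot(is(model, "UNetModel"))
  inputs <- if (inherits(batch, "SegmentBatch")) batch$inputs else batch
  stopifnot(length(dim(inputs)) == 3L)
  k <- dim(inputs)[3]
  p <- unet_forward(.modelPtr(model), .flattenBatch(inputs, seq_len(k)), k,
                    FALSE)
  array(p, dim = c(nrow(p), dim(inputs)[2], k))
}

#' Save / load a segmentation model
#'
#' The model state is written as a plain-text JSON file: architecture
#' configuration plus the full numeric state vector.
#'
#' @param model a [UNetModel-class].
#' @param path file path.
#' @return `loadUNet` returns the restored [UNetModel-class];
#'   `saveUNet` returns `path` invisibly.
#' @export
saveUNet <- function(model, path) {
  stopifnot(is(model, "UNetModel"))
  jsonlite::write_json(list(config = model@config[names(model@config)],
                            state = model@state),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveUNet
#' @export
loadUNet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(unetConfig, as.list(obj$config))
  model <- buildUNet(cfg, seed = 1L)
  unet_set_state(model@env$ptr, as.numeric(obj$state))
  new("UNetModel", config = unclass(cfg), state = as.numeric(obj$state),
      env = model@env)
}
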