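# Training protocol: AdamW with cosine-annealed learning rate, online
# geometric augmentation, hybrid CE + soft-Dice loss, per-epoch validation
# DSC, full single-device reproducibility given the seed.

#' Cosine-annealed learning rate
#'
#' Learning rate applied during epoch `e` (1-based) of `E`:
#' `minLr + 0.5 * (baseLr - minLr) * (1 + cos(pi * e / E))`. The half-way
#' epoch receives exactly `(baseLr + minLr) / 2` and the final epoch exactly
#' `minLr`.
#'
#' @param epoch current epoch (1..epochs).
#' @param epochs total epochs.
#' @param baseLr,minLr schedule endpoints.
#' @return learning rate for that epoch.
#' @export
cosineLr <- function(epoch, epochs, baseLr, minLr = 0) {
  minLr + 0.5 * (baseLr - minLr) * (1 + cos(pi * epoch / epochs))
}

meanForegroundDsc <- function(model, cases, numClasses, tta = "none") {
  cls <- seq_len(numClasses - 1L)
  acc <- matrix(NA_real_, length(cases), length(cls))
  for (i in seq_along(cases)) {
    pred <- predictSegmentation(model, cases[[i]]$image, tta = tta)$label
    for (j in seq_along(cls))
      acc[i, j] <- dsc(pred == cls[j], cases[[i]]$label == cls[j])
  }
  mean(colMeans(acc))
}

#' Train a segmentation model
#'
#' Runs the full protocol on an in-memory dataset: shuffled minibatches,
#' optional online augmentation, hybrid loss `alpha * CE + beta * softDice`,
#' AdamW updates with the cosine learning-rate schedule, and per-epoch
#' validation mean foreground DSC. The RNG is *not* reseeded here; seed the
#' session (or use [runTraining()]) for bitwise reproducibility.
#'
#' @param model a [SceafModel-class] (updated in place; also returned).
#' @param data list with `train` and `val`: lists of cases
#'   (`list(image, label)`).
#' @param config a [TrainConfig-class].
#' @param policy an [AugmentPolicy-class] used when `config@augment`.
#' @param verbose print per-epoch progress.
#' @param selectBest restore the weights of the epoch with the best
#'   validation DSC at the end (checkpoint selection by validation score);
#'   ignored when no validation split is provided.
#' @return list with `model`, `history` (data.frame: epoch, lr, loss,
#'   valDsc) and `bestEpoch`.
#' @export
trainModel <- function(model, data, config = trainConfig(),
                       policy = augmentPolicy(), verbose = FALSE,
                       selectBest = TRUE) {
  root <- model@net$root
  K <- model@config@numClasses
  refs <- nnParamRefs(root)
  opt <- nnAdamW(refs, lr = config@baseLr, weight_decay = config@weightDecay)
  train <- data$train
  n <- length(train)
  stopifnot(n >= 1)
  S <- dim(train[[1]]$image)[1]
  history <- NULL
  bestDsc <- -Inf
  bestState <- NULL
  bestEpoch <- NA_integer_
  for (epoch in seq_len(config@epochs)) {
    lr <- cosineLr(epoch, config@epochs, config@baseLr, config@minLr)
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = config@batchSize)) {
      idx <- ord[start:min(start + config@batchSize - 1L, n)]
      B <- length(idx)
      xb <- array(0, c(S, S, B, 1L))
      yb <- array(0L, c(S, S, B))
      for (b in seq_len(B)) {
        cs <- train[[idx[b]]]
        if (config@augment) {
          cs <- augmentSample(cs$image, cs$label, policy)
        }
        xb[, , b, 1] <- cs$image
        yb[, , b] <- cs$label
      }
      logits <- nnForward(root, xb, training = TRUE)
      ls <- hybridLoss(logits, yb, config@alpha, config@beta, grad = TRUE)
      if (!is.finite(ls$loss))
        stop(sprintf("non-finite loss at epoch %d (ce = %g, dice = %g); aborting",
                     epoch, ls$ce, ls$dice))
      nnZeroGrads(root)
      nnBackward(root, ls$grad)
      opt$step(lr)
      losses <- c(losses, ls$loss)
    }
    valDsc <- if (length(data$val) > 0)
      meanForegroundDsc(model, data$val, K) else NA_real_
    if (selectBest && is.finite(valDsc) && valDsc > bestDsc) {
      bestDsc <- valDsc
      bestState <- nnGetState(root)
      bestEpoch <- epoch
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr,
                                loss = mean(losses), valDsc = valDsc))
    if (verbose)
      message(sprintf("epoch %d/%d lr %.5f loss %.4f val DSC %.4f",
                      epoch, config@epochs, lr, mean(losses), valDsc))
  }
  if (!is.null(bestState)) nnSetState(root, bestState)
  list(model = model, history = history, bestEpoch = bestEpoch)
}

#' Seeded end-to-end training run
#'
#' Seeds the RNG with `trainCfg@seed`, builds a fresh model and trains it.
#' Two calls with identical configurations and data are bitwise identical.
#'
#' @param modelCfg a [ModelConfig-class].
#' @param trainCfg a [TrainConfig-class].
#' @param data dataset as for [trainModel()]; if `NULL`, generated from
#'   `spec`.
#' @param spec a [SyntheticSpec-class] used when `data` is `NULL`.
#' @param policy an [AugmentPolicy-class].
#' @param verbose print progress.
#' @return list with `model`, `history` and `data`.
#' @export
runTraining <- function(modelCfg, trainCfg, data = NULL, spec = NULL,
                        policy = augmentPolicy(), verbose = FALSE) {
  if (is.null(data)) {
    stopifnot(!is.null(spec))
    data <- generateDataset(spec)
  }
  set.seed(trainCfg@seed)
  model <- buildModel(modelCfg)
  fit <- trainModel(model, data, trainCfg, policy, verbose)
  list(model = fit$model, history = fit$history, data = data,
       bestEpoch = fit$bestEpoch)
}

#' Desk-scale default configurations
#'
#' The small reference setup used throughout the examples and the package's
#' own end-to-end verification: 64 x 64 phantoms with K = 4 classes, a
#' narrow backbone (stages 8/16/32/64), decoder widths 32/16/8/8, the gated
#' enhancement module at D3 and D2, and a short cosine schedule.
#'
#' @return `smallModelConfig()`: a [ModelConfig-class];
#'   `smallTrainConfig()`: a [TrainConfig-class].
#' @export
smallModelConfig <- function() {
  modelConfig(
    backbone = backboneConfig(inChannels = 1L,
                              stageChannels = c(8L, 16L, 32L, 64L),
                              blocksPerStage = 2L),
    numClasses = 4L,
    decoderChannels = c(32L, 16L, 8L, 8L),
    sceafPlacement = c("D3", "D2"),
    eafReduction = 4L)
}

#' @rdname smallModelConfig
#' @param epochs,batchSize,baseLr overrides of the short-schedule defaults.
#' @export
smallTrainConfig <- function(epochs = 20L, batchSize = 12L, baseLr = 5e-3) {
  trainConfig(epochs = epochs, baseLr = baseLr, minLr = 0,
              batchSize = batchSize, alpha = 0.5, beta = 0.5,
              seed = 1234L, inputSize = 64L, augment = TRUE)
}

#' Checkpoint a model to disk (weights + configuration)
#'
#' @param model a [SceafModel-class].
#' @param path output file (RDS).
#' @param extra optional list stored alongside (e.g. training history).
#' @export
saveCheckpoint <- function(model, path, extra = NULL) {
  saveRDS(list(config = model@config, state = nnGetState(model@net$root),
               extra = extra), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @return `loadCheckpoint()`: list with `model` and `extra`.
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  model <- buildModel(ck$config)
  nnSetState(model@net$root, ck$state)
  list(model = model, extra = ck$extra)
}
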