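#' @import methods
NULL

## ---------------------------------------------------------------------------
## Configuration classes
## ---------------------------------------------------------------------------

#' Backbone configuration
#'
#' Describes the reference hierarchical convolutional encoder. The encoder
#' contract is four stage features `E1..E4` with spatial sizes
#' `H/2, H/4, H/8, H/16` and non-decreasing channel counts; any encoder
#' honouring that contract can be plugged in behind [encode()].
#'
#' @slot inChannels number of input image channels (1 for grayscale slices).
#' @slot stageChannels integer vector of four stage channel counts `c1..c4`.
#' @slot blocksPerStage number of 3x3 conv + BN + GELU blocks per stage;
#'   a scalar or one count per stage.
#' @slot stemDownsample stem downsampling factor (fixed at 2: a strided conv).
#' @exportClass BackboneConfig
setClass("BackboneConfig",
  representation(inChannels = "integer", stageChannels = "integer",
                 blocksPerStage = "integer", stemDownsample = "integer"),
  validity = function(object) {
    c <- object@stageChannels
    if (length(c) != 4) return("stageChannels must have length 4")
    if (any(c <= 0)) return("stage channels must be positive")
    if (is.unsorted(c)) return("stage channels must be non-decreasing")
    if (object@inChannels < 1) return("inChannels must be >= 1")
    if (!length(object@blocksPerStage) %in% c(1L, 4L))
      return("blocksPerStage must have length 1 or 4")
    if (any(object@blocksPerStage < 1)) return("blocksPerStage must be >= 1")
    if (object@stemDownsample != 2L) return("stemDownsample must be 2")
    TRUE
  })

#' @param inChannels,stageChannels,blocksPerStage,stemDownsample see slots.
#' @rdname BackboneConfig-class
#' @export
backboneConfig <- function(inChannels = 1L,
                           stageChannels = c(32L, 64L, 128L, 256L),
                           blocksPerStage = 2L, stemDownsample = 2L) {
  new("BackboneConfig", inChannels = as.integer(inChannels),
      stageChannels = as.integer(stageChannels),
      blocksPerStage = as.integer(blocksPerStage),
      stemDownsample = as.integer(stemDownsample))
}

#' Full model configuration for the edge-attentive gated-fusion U-Net
#'
#' Collects every architecture hyperparameter: the backbone layout, the
#' edge-attention skip modules (per-skip enable flags and reduction ratio
#' `r`), decoder channel widths, the placement set of the gated
#' spatial/channel enhancement module among decoder stages `D4..D1`
#' (deepest to shallowest), the branch fusion strategy, and the internal
#' knobs of the MSAG and CAM blocks.
#'
#' @slot backbone a [BackboneConfig-class].
#' @slot numClasses number of segmentation classes K (logit channels).
#' @slot eafEnabled logical(3): edge-attention module on skips E1, E2, E3.
#' @slot eafReduction channel reduction ratio r of the edge-attention MLP.
#' @slot decoderChannels integer(4): output channels of decoder stages
#'   D4, D3, D2, D1 (deepest first).
#' @slot sceafPlacement character subset of `c("D4","D3","D2","D1")`.
#' @slot fusion one of `"gated_weighted_sum"`, `"cascade"`, `"addition"`,
#'   `"concatenation"`, `"multiplication"`.
#' @slot useMsag,useCam module switches for the two decoder branches.
#' @slot msagMcb,msagDg,msagGft switches for MSAG internals (multi-scale
#'   conv block, dual gating, gated feature transform).
#' @slot cIntRatio intermediate channel ratio `C_int = ratio * Cx` in MSAG.
#' @slot camKernel depthwise kernel size of the CAM block (3, 5 or 7).
#' @slot seReduction squeeze-and-excitation bottleneck reduction.
#' @slot layerScaleInit initial LayerScale value (ConvNeXt convention).
#' @slot dropPathRate stochastic-depth rate on the CAM residual branch.
#' @slot mcbKernels depthwise kernel sizes of the multi-scale conv block.
#' @slot shuffleGroups channel shuffle groups in the upsampling block.
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(backbone = "BackboneConfig", numClasses = "integer",
                 eafEnabled = "logical", eafReduction = "integer",
                 decoderChannels = "integer", sceafPlacement = "character",
                 fusion = "character", useMsag = "logical", useCam = "logical",
                 msagMcb = "logical", msagDg = "logical", msagGft = "logical",
                 cIntRatio = "numeric", camKernel = "integer",
                 seReduction = "integer", layerScaleInit = "numeric",
                 dropPathRate = "numeric", mcbKernels = "integer",
                 shuffleGroups = "integer"),
  validity = function(object) {
    if (object@numClasses < 2) return("numClasses must be >= 2")
    if (length(object@eafEnabled) != 3)
      return("eafEnabled must be logical(3) (skips E1..E3)")
    if (object@eafReduction < 1) return("eafReduction must be >= 1")
    if (length(object@decoderChannels) != 4 || any(object@decoderChannels <= 0))
      return("decoderChannels must be 4 positive counts (D4..D1)")
    if (!all(object@sceafPlacement %in% c("D4", "D3", "D2", "D1")))
      return("sceafPlacement must be a subset of D4..D1")
    if (anyDuplicated(object@sceafPlacement))
      return("sceafPlacement must not contain duplicates")
    if (!object@fusion %in% c("gated_weighted_sum", "cascade", "addition",
                              "concatenation", "multiplication"))
      return(sprintf("unknown fusion strategy '%s'", object@fusion))
    if (length(object@sceafPlacement) > 0 && !(object@useMsag || object@useCam))
      return("sceafPlacement non-empty requires MSAG or CAM enabled")
    if (object@useMsag && "D1" %in% object@sceafPlacement)
      return(paste("SCEAF placement at D1 is invalid: stage D1 has no skip",
                   "connection, and the MSAG branch requires the global",
                   "guiding feature g"))
    if (!object@camKernel %in% c(3L, 5L, 7L))
      return("camKernel must be one of 3, 5, 7")
    if (object@cIntRatio <= 0 || object@cIntRatio > 1)
      return("cIntRatio must be in (0, 1]")
    if (any(object@decoderChannels %% object@shuffleGroups != 0))
      return("all decoder channels must be divisible by shuffleGroups")
    sc <- object@backbone@stageChannels
    if (any(object@eafEnabled & (sc[1:3] %% object@eafReduction != 0)))
      return("skip channels must be divisible by eafReduction")
    if (object@dropPathRate < 0 || object@dropPathRate > 1)
      return("dropPathRate must be in [0, 1]")
    TRUE
  })

#' @param backbone,numClasses,eafEnabled,eafReduction,decoderChannels see slots.
#' @param sceafPlacement,fusion,useMsag,useCam,msagMcb,msagDg,msagGft see slots.
#' @param cIntRatio,camKernel,seReduction,layerScaleInit,dropPathRate see slots.
#' @param mcbKernels,shuffleGroups see slots.
#' @rdname ModelConfig-class
#' @export
modelConfig <- function(backbone = backboneConfig(), numClasses = 9L,
                        eafEnabled = rep(TRUE, 3), eafReduction = 4L,
                        decoderChannels = c(128L, 64L, 32L, 32L),
                        sceafPlacement = c("D3", "D2"),
                        fusion = "gated_weighted_sum",
                        useMsag = TRUE, useCam = TRUE,
                        msagMcb = TRUE, msagDg = TRUE, msagGft = TRUE,
                        cIntRatio = 0.5, camKernel = 3L, seReduction = 16L,
                        layerScaleInit = 1e-6, dropPathRate = 0,
                        mcbKernels = c(1L, 3L, 5L), shuffleGroups = 4L) {
  new("ModelConfig", backbone = backbone, numClasses = as.integer(numClasses),
      eafEnabled = as.logical(eafEnabled), eafReduction = as.integer(eafReduction),
      decoderChannels = as.integer(decoderChannels),
      sceafPlacement = as.character(sceafPlacement), fusion = fusion,
      useMsag = isTRUE(useMsag), useCam = isTRUE(useCam),
      msagMcb = isTRUE(msagMcb), msagDg = isTRUE(msagDg),
      msagGft = isTRUE(msagGft), cIntRatio = cIntRatio,
      camKernel = as.integer(camKernel), seReduction = as.integer(seReduction),
      layerScaleInit = layerScaleInit, dropPathRate = dropPathRate,
      mcbKernels = as.integer(mcbKernels),
      shuffleGroups = as.integer(shuffleGroups))
}

#' Toggle the three architecture modules of a configuration
#'
#' Convenience for ablation sweeps: switches the MSAG branch, the CAM branch
#' and the edge-attention skip modules on or off. When both decoder branches
#' are disabled the placement set is cleared (the decoder then fuses skips by
#' 1x1-projected addition only).
#'
#' @param config a [ModelConfig-class].
#' @param msag,cam,eaf logical switches; `NA` leaves a switch unchanged.
#' @return the modified [ModelConfig-class].
#' @export
setModules <- function(config, msag = NA, cam = NA, eaf = NA) {
  if (!is.na(msag)) config@useMsag <- isTRUE(msag)
  if (!is.na(cam)) config@useCam <- isTRUE(cam)
  if (!is.na(eaf)) config@eafEnabled <- rep(isTRUE(eaf), 3)
  if (!config@useMsag && !config@useCam) config@sceafPlacement <- character(0)
  validObject(config)
  config
}

## ---------------------------------------------------------------------------
## Budget report
## ---------------------------------------------------------------------------

#' Parameter / FLOP budget report
#'
#' Produced by [countBudget()]. FLOPs follow the 2 x multiply-accumulate
#' convention over convolution and linear layers, recorded in the
#' `convention` slot so comparisons against budgets counted as 1 x MAC can be
#' made by halving.
#'
#' @slot totalParams total trainable scalars.
#' @slot totalMacs total multiply-accumulates at `inputSize`.
#' @slot totalFlops `2 * totalMacs`.
#' @slot inputSize spatial input size the MACs were traced at.
#' @slot convention FLOP counting convention string.
#' @slot perModule data.frame: per-module parameter and MAC totals.
#' @exportClass BudgetReport
setClass("BudgetReport",
  representation(totalParams = "numeric", totalMacs = "numeric",
                 totalFlops = "numeric", inputSize = "integer",
                 convention = "character", perModule = "data.frame"),
  validity = function(object) {
    if (abs(sum(object@perModule$params) - object@totalParams) > 0.5)
      return("per-module parameter entries must sum to the total")
    if (abs(sum(object@perModule$macs) - object@totalMacs) > 0.5)
      return("per-module MAC entries must sum to the total")
    if (abs(object@totalFlops - 2 * object@totalMacs) > 0.5)
      return("totalFlops must equal 2 * totalMacs")
    TRUE
  })

## ---------------------------------------------------------------------------
## Training / augmentation / synthetic data configuration
## ---------------------------------------------------------------------------

#' Training protocol configuration
#'
#' Mirrors the reference training protocol: AdamW with cosine-annealed
#' learning rate, batch size 24, hybrid cross-entropy + soft-Dice loss with
#' weights `alpha` and `beta` (0.5/0.5 for abdominal CT style runs, 0.3/0.7
#' for cardiac MR style runs), a fixed seed of 1234, and 224 x 224 inputs.
#'
#' @slot epochs,baseLr,minLr,batchSize optimizer schedule parameters.
#' @slot alpha,beta hybrid loss weights (cross-entropy, soft Dice).
#' @slot weightDecay decoupled weight decay on convolution weights.
#' @slot seed RNG seed controlling initialization, batching and augmentation.
#' @slot inputSize model input side length (divisible by 16).
#' @slot augment apply the online geometric augmentation policy.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(epochs = "integer", baseLr = "numeric", minLr = "numeric",
                 batchSize = "integer", alpha = "numeric", beta = "numeric",
                 weightDecay = "numeric", seed = "integer",
                 inputSize = "integer", augment = "logical"),
  validity = function(object) {
    if (object@alpha < 0 || object@beta < 0)
      return("loss weights alpha and beta must be >= 0")
    if (object@minLr > object@baseLr) return("minLr must be <= baseLr")
    if (object@epochs < 1) return("epochs must be >= 1")
    if (object@inputSize %% 16 != 0) return("inputSize must be divisible by 16")
    TRUE
  })

#' @param epochs,baseLr,minLr,batchSize,alpha,beta,weightDecay,seed see slots.
#' @param inputSize,augment see slots.
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(epochs = 30L, baseLr = 1e-3, minLr = 0,
                        batchSize = 24L, alpha = 0.5, beta = 0.5,
                        weightDecay = 0.01, seed = 1234L, inputSize = 224L,
                        augment = TRUE) {
  new("TrainConfig", epochs = as.integer(epochs), baseLr = baseLr,
      minLr = minLr, batchSize = as.integer(batchSize), alpha = alpha,
      beta = beta, weightDecay = weightDecay, seed = as.integer(seed),
      inputSize = as.integer(inputSize), augment = isTRUE(augment))
}

#' Online geometric augmentation policy
#'
#' With probability `pGeo` a sample receives a rotation by a uniform multiple
#' of 90 degrees combined with a random horizontal-or-vertical flip;
#' otherwise, with conditional probability `pSmallRot`, a continuous planar
#' rotation uniform in `[-maxAngle, +maxAngle]` degrees (bilinear for the
#' image, nearest for the label map); otherwise the sample is unchanged.
#'
#' @slot pGeo probability of the rot90 + flip branch.
#' @slot pSmallRot conditional probability of the small-rotation branch.
#' @slot maxAngle small-rotation range in degrees.
#' @exportClass AugmentPolicy
setClass("AugmentPolicy",
  representation(pGeo = "numeric", pSmallRot = "numeric", maxAngle = "numeric"),
  validity = function(object) {
    p <- c(object@pGeo, object@pSmallRot)
    if (any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
    if (object@maxAngle < 0) return("maxAngle must be >= 0")
    TRUE
  })

#' @param pGeo,pSmallRot,maxAngle see slots.
#' @rdname AugmentPolicy-class
#' @export
augmentPolicy <- function(pGeo = 0.5, pSmallRot = 0.25, maxAngle = 20) {
  new("AugmentPolicy", pGeo = pGeo, pSmallRot = pSmallRot, maxAngle = maxAngle)
}

#' Synthetic organ-phantom specification
#'
#' Parameters of the multi-class phantom generator used for desk-scale
#' training and evaluation. Classes are background plus up to three disjoint
#' foreground structures: a large elliptical blob, a thin annulus (ring
#' thickness 1-4 px, stressing boundary metrics the way thin-walled anatomy
#' does), and a small ellipse. Class-conditional mean intensities are evenly
#' spaced over `contrast` and separated by at least `2 * noiseSd`.
#'
#' @slot imageSize square image side (divisible by 16).
#' @slot numClasses K including background (2..4).
#' @slot nTrain,nVal,nTest split sizes.
#' @slot noiseSd additive Gaussian noise standard deviation.
#' @slot contrast range of class mean intensities, `c(low, high)` in [0, 1].
#' @slot dropoutProb probability that a small foreground structure is omitted
#'   from a case (emulating missing organs); kept below 0.1 so every class is
#'   present with probability >= 0.9.
#' @slot seed base RNG seed of the generator.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(imageSize = "integer", numClasses = "integer",
                 nTrain = "integer", nVal = "integer", nTest = "integer",
                 noiseSd = "numeric", contrast = "numeric",
                 dropoutProb = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@imageSize %% 16 != 0) return("imageSize must be divisible by 16")
    if (object@numClasses < 2 || object@numClasses > 4)
      return("numClasses must be in 2..4")
    if (length(object@contrast) != 2 || diff(object@contrast) <= 0)
      return("contrast must be an increasing range c(low, high)")
    if (any(object@contrast < 0 | object@contrast > 1))
      return("contrast must lie in [0, 1]")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@dropoutProb < 0 || object@dropoutProb > 0.1)
      return("dropoutProb must be in [0, 0.1]")
    k <- object@numClasses
    if (k > 1 && object@noiseSd > 0 &&
        diff(object@contrast) / (k - 1) < 2 * object@noiseSd)
      return("class mean spacing must be >= 2 * noiseSd")
    TRUE
  })

#' @param imageSize,numClasses,nTrain,nVal,nTest,noiseSd,contrast see slots.
#' @param dropoutProb,seed see slots.
#' @rdname SyntheticSpec-class
#' @export
syntheticSpec <- function(imageSize = 64L, numClasses = 4L, nTrain = 400L,
                          nVal = 40L, nTest = 60L, noiseSd = 0.05,
                          contrast = c(0.15, 0.95), dropoutProb = 0.05,
                          seed = 1234L) {
  new("SyntheticSpec", imageSize = as.integer(imageSize),
      numClasses = as.integer(numClasses), nTrain = as.integer(nTrain),
      nVal = as.integer(nVal), nTest = as.integer(nTest), noiseSd = noiseSd,
      contrast = contrast, dropoutProb = dropoutProb, seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Model wrapper
## ---------------------------------------------------------------------------

#' Trained / trainable segmentation model
#'
#' Wraps the network state (a reference-semantics module tree) together with
#' its [ModelConfig-class]. Obtain one with [buildModel()].
#'
#' @slot net environment holding the module tree.
#' @slot config the architecture configuration.
#' @exportClass SceafModel
setClass("SceafModel",
  representation(net = "environment", config = "ModelConfig"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "BackboneConfig", function(object) {
  cat("Reference backbone: in =", object@inChannels,
      "| stages [", paste(object@stageChannels, collapse = ", "),
      "] x", paste(rep(object@blocksPerStage, length.out = 4),
                   collapse = "/"), "blocks\n")
})

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig (edge-attentive gated-fusion U-Net)\n")
  cat("  classes:", object@numClasses, "\n")
  cat("  encoder stages: [",
      paste(object@backbone@stageChannels, collapse = ", "), "]\n")
  cat("  decoder stages D4..D1: [",
      paste(object@decoderChannels, collapse = ", "), "]\n")
  cat("  EAF skips:", paste(ifelse(object@eafEnabled, "on", "off"),
                            collapse = "/"),
      " (r =", object@eafReduction, ")\n")
  cat("  SCEAF placement: {", paste(object@sceafPlacement, collapse = ", "),
      "} fusion:", object@fusion, "\n")
  cat("  branches: MSAG =", object@useMsag, "| CAM =", object@useCam,
      "(kernel", object@camKernel, ")\n")
})

setMethod("show", "BudgetReport", function(object) {
  cat(sprintf("Budget at %dx%d input (%s)\n", object@inputSize,
              object@inputSize, object@convention))
  cat(sprintf("  params: %.4f M   FLOPs: %.4f G   (MACs: %.4f G)\n",
              object@totalParams / 1e6, object@totalFlops / 1e9,
              object@totalMacs / 1e9))
  pm <- object@perModule
  for (i in seq_len(nrow(pm))) {
    cat(sprintf("  %-10s %10.4f M params %10.4f G FLOPs\n", pm$module[i],
                pm$params[i] / 1e6, 2 * pm$macs[i] / 1e9))
  }
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %dx%d, K = %d, splits %d/%d/%d, noise sd %.3f\n",
              object@imageSize, object@imageSize, object@numClasses,
              object@nTrain, object@nVal, object@nTest, object@noiseSd))
})

setMethod("show", "SceafModel", function(object) {
  cat("SceafModel with", format(nnParamCount(object@net$root), big.mark = ","),
      "trainable parameters\n")
  show(object@config)
})
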