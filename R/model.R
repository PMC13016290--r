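# Full model assembly: backbone + EAF-refined skips + channel-shuffle
# upsampling decoder with the gated spatial/channel enhancement module at the
# configured stages.
#
# Decoder stages run D4 (deepest) -> D1. Stage Dk upsamples, fuses the skip
# at its output scale (D4<-E3, D3<-E2, D2<-E1; D1 has none) by 1x1-projected
# addition, and, if the stage is in the placement set, refines the result
# with the MSAG and/or CAM branches. The projected addition is part of the
# base decoder and is kept in every variant so that enabling a module always
# changes the budget by exactly that module's standalone cost.

stageSkipIndex <- c(D4 = 3L, D3 = 2L, D2 = 1L, D1 = 0L)

buildModelNet <- function(config) {
  validObject(config)
  bb <- config@backbone
  sc <- bb@stageChannels
  dc <- config@decoderChannels  # D4, D3, D2, D1
  K <- config@numClasses
  m <- nnModule("sceafnet")
  m$config <- config
  ch <- list(backbone = buildBackboneNet(bb))
  for (i in 1:3) {
    if (config@eafEnabled[i])
      ch[[paste0("eaf", i)]] <- eafBlock(sc[i], config@eafReduction)
  }
  cin <- c(sc[4], dc[1], dc[2], dc[3])  # inputs of csu4..csu1
  for (s in 1:4) {
    st <- paste0("D", 5L - s)  # s=1 -> D4
    ch[[paste0("csu", 5L - s)]] <-
      csuBlock(cin[s], dc[s], config@shuffleGroups)
  }
  for (st in c("D4", "D3", "D2")) {
    si <- stageSkipIndex[[st]]
    dst <- dc[5L - si - 1L]  # D4 -> dc[1], D3 -> dc[2], D2 -> dc[3]
    ch[[paste0("proj", st)]] <- nnConv(sc[si], dst, 1L)
  }
  for (st in config@sceafPlacement) {
    si <- stageSkipIndex[[st]]
    dst <- dc[c(D4 = 1L, D3 = 2L, D2 = 3L, D1 = 4L)[[st]]]
    if (config@useMsag && si > 0) {
      cint <- max(1L, as.integer(round(config@cIntRatio * dst)))
      ch[[paste0("msag", st)]] <-
        msagBlock(sc[si], dst, cint, config@mcbKernels,
                  useMcb = config@msagMcb, useDg = config@msagDg,
                  useGft = config@msagGft)
    }
    if (config@useCam) {
      ch[[paste0("cam", st)]] <-
        camBlock(dst, config@camKernel, config@seReduction,
                 layerScaleInit = config@layerScaleInit,
                 dropPathRate = config@dropPathRate)
    }
    if (config@useMsag && config@useCam && si > 0 &&
        config@fusion == "concatenation") {
      ch[[paste0("fusecat", st)]] <- nnConv(2L * dst, dst, 1L)
    }
  }
  ch$head <- nnConv(dc[4], K, 1L)
  m$children <- ch
  m
}

nnForward.nn_sceafnet <- function(m, x, training = FALSE) {
  cfg <- m$config
  ch <- m$children
  # grayscale slices can feed a 3-channel encoder by replication
  if (dim(x)[4] == 1L && cfg@backbone@inChannels == 3L)
    x <- x[, , , c(1L, 1L, 1L), drop = FALSE]
  checkImageInput(x)
  E <- nnForward(ch$backbone, x, training)
  skips <- vector("list", 3)
  for (i in 1:3) {
    skips[[i]] <- if (cfg@eafEnabled[i])
      nnForward(ch[[paste0("eaf", i)]], E[[i]], training) else E[[i]]
  }
  stcache <- list()
  h <- E[[4]]
  dcIdx <- c(D4 = 1L, D3 = 2L, D2 = 3L, D1 = 4L)
  for (st in c("D4", "D3", "D2", "D1")) {
    h <- nnForward(ch[[paste0("csu", substr(st, 2, 2))]], h, training)
    si <- stageSkipIndex[[st]]
    placed <- st %in% cfg@sceafPlacement
    if (si > 0) {
      ps <- nnForward(ch[[paste0("proj", st)]], skips[[si]], training)
      xp <- h + ps
      if (placed && cfg@useMsag && cfg@useCam) {
        Ym <- nnForward(ch[[paste0("msag", st)]],
                        list(g = skips[[si]], x = xp), training)
        if (cfg@fusion == "cascade") {
          out <- nnForward(ch[[paste0("cam", st)]], Ym, training)
          stcache[[st]] <- list(mode = "cascade")
        } else {
          Yc <- nnForward(ch[[paste0("cam", st)]], xp, training)
          if (cfg@fusion == "gated_weighted_sum") {
            w <- 1 / (1 + exp(-Ym))
            out <- w * Ym + (1 - w) * Yc
            stcache[[st]] <- list(mode = "gated", w = w, Ym = Ym, Yc = Yc)
          } else if (cfg@fusion == "addition") {
            out <- Ym + Yc
            stcache[[st]] <- list(mode = "addition")
          } else if (cfg@fusion == "multiplication") {
            out <- Ym * Yc
            stcache[[st]] <- list(mode = "multiplication", Ym = Ym, Yc = Yc)
          } else {  # concatenation
            out <- nnForward(ch[[paste0("fusecat", st)]],
                             catChannels(Ym, Yc), training)
            stcache[[st]] <- list(mode = "concat")
          }
        }
      } else if (placed && cfg@useMsag) {
        out <- nnForward(ch[[paste0("msag", st)]],
                         list(g = skips[[si]], x = xp), training)
        stcache[[st]] <- list(mode = "msag")
      } else if (placed && cfg@useCam) {
        out <- nnForward(ch[[paste0("cam", st)]], xp, training)
        stcache[[st]] <- list(mode = "cam")
      } else {
        out <- xp
        stcache[[st]] <- list(mode = "plain")
      }
      h <- out
    } else {
      if (placed && cfg@useCam) {
        h <- nnForward(ch[[paste0("cam", st)]], h, training)
        stcache[[st]] <- list(mode = "cam_noskip")
      } else {
        stcache[[st]] <- list(mode = "none")
      }
    }
  }
  m$cache <- list(stages = stcache)
  nnForward(ch$head, h, training)
}

nnBackward.nn_sceafnet <- function(m, dy) {
  cfg <- m$config
  ch <- m$children
  stc <- m$cache$stages
  dh <- nnBackward(ch$head, dy)
  dskips <- vector("list", 3)
  addg <- function(a, b) if (is.null(a)) b else a + b
  for (st in c("D1", "D2", "D3", "D4")) {
    si <- stageSkipIndex[[st]]
    cc <- stc[[st]]
    if (si > 0) {
      dOut <- dh
      dxp <- NULL
      if (cc$mode == "gated") {
        s <- cc$w
        dYm <- dOut * (s + (cc$Ym - cc$Yc) * s * (1 - s))
        dYc <- dOut * (1 - s)
      } else if (cc$mode == "addition") {
        dYm <- dOut; dYc <- dOut
      } else if (cc$mode == "multiplication") {
        dYm <- dOut * cc$Yc; dYc <- dOut * cc$Ym
      } else if (cc$mode == "concat") {
        C <- dim(dOut)[4]
        dcat <- nnBackward(ch[[paste0("fusecat", st)]], dOut)
        dYm <- dcat[, , , seq_len(C), drop = FALSE]
        dYc <- dcat[, , , C + seq_len(C), drop = FALSE]
      } else if (cc$mode == "cascade") {
        dYm <- nnBackward(ch[[paste0("cam", st)]], dOut)
        dYc <- NULL
      } else if (cc$mode == "msag") {
        dYm <- dOut; dYc <- NULL
      } else if (cc$mode == "cam") {
        dYm <- NULL
        dxp <- nnBackward(ch[[paste0("cam", st)]], dOut)
      } else {  # plain
        dYm <- NULL
        dxp <- dOut
      }
      if (!is.null(dYm) && cc$mode != "cam") {
        r <- nnBackward(ch[[paste0("msag", st)]], dYm)
        dxp <- addg(dxp, r$dx)
        if (!is.null(r$dg)) dskips[[si]] <- addg(dskips[[si]], r$dg)
      }
      if (!is.null(cc$mode) && cc$mode %in%
            c("gated", "addition", "multiplication", "concat")) {
        dxp <- addg(dxp, nnBackward(ch[[paste0("cam", st)]], dYc))
      }
      dskips[[si]] <- addg(dskips[[si]],
                           nnBackward(ch[[paste0("proj", st)]], dxp))
      dh <- dxp
    } else {
      if (cc$mode == "cam_noskip")
        dh <- nnBackward(ch[[paste0("cam", st)]], dh)
    }
    dh <- nnBackward(ch[[paste0("csu", substr(st, 2, 2))]], dh)
  }
  dE <- vector("list", 4)
  dE[[4]] <- dh
  for (i in 1:3) {
    if (is.null(dskips[[i]])) next
    dE[[i]] <- if (cfg@eafEnabled[i])
      nnBackward(ch[[paste0("eaf", i)]], dskips[[i]]) else dskips[[i]]
  }
  nnBackward(ch$backbone, dE)
}

#' Build the full segmentation model
#'
#' Assembles the encoder, the edge-attention skip modules and the decoder
#' into a trainable network. Weights are initialized from the current RNG
#' state; call [set.seed()] first for reproducible builds.
#'
#' @param config a [ModelConfig-class].
#' @return a [SceafModel-class].
#' @export
buildModel <- function(config = modelConfig()) {
  env <- new.env(parent = emptyenv())
  env$root <- buildModelNet(config)
  new("SceafModel", net = env, config = config)
}

#' Forward pass producing class logits
#'
#' @param model a [SceafModel-class].
#' @param image array `(H, W)`, `(H, W, C)` or batched `(H, W, N, C)`.
#' @param training training-mode flag (batch statistics, drop path).
#' @return logits array `(H, W, N, K)` at full input resolution (batched
#'   input) or `(H, W, K)` for a single image.
#' @export
modelLogits <- function(model, image, training = FALSE) {
  x <- nnBatch(image)
  single <- length(dim(image)) < 4
  y <- nnForward(model@net$root, x, training)
  if (single) nnUnbatch(y) else y
}

## ---------------------------------------------------------------------------
## Budget accounting
## ---------------------------------------------------------------------------

modelDescribe <- function(config, inputSize = 224L) {
  net <- withLazyModules(buildModelNet(config))
  cfg <- config
  sc <- cfg@backbone@stageChannels
  dc <- cfg@decoderChannels
  S <- as.integer(inputSize)
  ch <- net$children
  groups <- list()
  add <- function(groups, module, rows) {
    if (is.null(rows)) return(groups)
    groups[[module]] <- rbind(groups[[module]], rows)
    groups
  }
  bb <- nnDescribe(ch$backbone, c(S, S, cfg@backbone@inChannels))
  groups <- add(groups, "backbone", bb$rows)
  eShape <- list(c(S %/% 2L, S %/% 2L, sc[1]), c(S %/% 4L, S %/% 4L, sc[2]),
                 c(S %/% 8L, S %/% 8L, sc[3]), c(S %/% 16L, S %/% 16L, sc[4]))
  for (i in 1:3) {
    nm <- paste0("eaf", i)
    if (!is.null(ch[[nm]]))
      groups <- add(groups, "eaf", nnDescribe(ch[[nm]], eShape[[i]])$rows)
  }
  # decoder spatial sizes: output of D4..D1
  outS <- c(S %/% 8L, S %/% 4L, S %/% 2L, S)
  inShape <- eShape[[4]]
  dcIdx <- c(D4 = 1L, D3 = 2L, D2 = 3L, D1 = 4L)
  for (st in c("D4", "D3", "D2", "D1")) {
    k <- dcIdx[[st]]
    dd <- nnDescribe(ch[[paste0("csu", substr(st, 2, 2))]], inShape)
    groups <- add(groups, "decoder", dd$rows)
    stShape <- dd$out
    si <- stageSkipIndex[[st]]
    if (si > 0) {
      groups <- add(groups, "decoder",
                    nnDescribe(ch[[paste0("proj", st)]],
                               c(stShape[1], stShape[2], sc[si]))$rows)
    }
    if (st %in% cfg@sceafPlacement) {
      nm <- paste0("msag", st)
      if (!is.null(ch[[nm]]))
        groups <- add(groups, "msag", nnDescribe(ch[[nm]], stShape)$rows)
      nm <- paste0("cam", st)
      if (!is.null(ch[[nm]]))
        groups <- add(groups, "cam", nnDescribe(ch[[nm]], stShape)$rows)
      nm <- paste0("fusecat", st)
      if (!is.null(ch[[nm]]))
        groups <- add(groups, "fusion",
                      nnDescribe(ch[[nm]],
                                 c(stShape[1], stShape[2],
                                   2L * stShape[3]))$rows)
    }
    inShape <- stShape
  }
  groups <- add(groups, "decoder",
                nnDescribe(ch$head, c(S, S, dc[4]))$rows)
  groups
}

#' Parameter and FLOP budget of a model configuration
#'
#' Counts trainable parameters and multiply-accumulates analytically from
#' the architecture at a stated input size (no weights are allocated).
#' FLOPs are reported as 2 x MAC over convolution and linear layers; the
#' convention is recorded in the report so a 1 x MAC comparison can be made
#' by halving.
#'
#' @param config a [ModelConfig-class] (or a [SceafModel-class], whose
#'   configuration is used).
#' @param inputSize square input side, default 224.
#' @return a [BudgetReport-class].
#' @examples
#' countBudget(modelConfig(numClasses = 4,
#'   backbone = backboneConfig(stageChannels = c(8, 16, 32, 64)),
#'   decoderChannels = c(32, 16, 8, 8)), inputSize = 64)
#' @export
countBudget <- function(config, inputSize = 224L) {
  if (is(config, "SceafModel")) config <- config@config
  groups <- modelDescribe(config, inputSize)
  pm <- data.frame(
    module = names(groups),
    params = vapply(groups, function(g) sum(g$params), 0),
    macs = vapply(groups, function(g) sum(g$macs), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  new("BudgetReport",
      totalParams = sum(pm$params), totalMacs = sum(pm$macs),
      totalFlops = 2 * sum(pm$macs), inputSize = as.integer(inputSize),
      convention = "2 x multiply-accumulate over conv/linear layers",
      perModule = pm)
}
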