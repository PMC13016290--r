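# The architecture's bespoke blocks. Each is an nn_module with hand-wired
# forward/backward and a describe() used by the budget engine.

catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

## ---------------------------------------------------------------------------
## Edge attention fusion (skip connection refinement)
## ---------------------------------------------------------------------------

#' Edge attention fusion (EAF) block
#'
#' Refines an encoder skip feature before it reaches the decoder. A learned
#' depthwise 3x3 convolution acts as a high-pass filter producing an edge
#' response `S1`; a bottleneck MLP (1x1 convs `C -> C/r -> C` with GELU then
#' sigmoid) turns it into an edge attention map `S2` in (0,1); the input is
#' gated by `S2`, concatenated with itself and compressed back to C channels
#' (1x1 conv + BN + GELU); a final depthwise 3x3 + BN + GELU refines the
#' result. Output shape equals input shape.
#'
#' @param channels feature channels C.
#' @param reduction channel reduction ratio r of the attention MLP
#'   (C must be divisible by r).
#' @return an internal network module; apply with [moduleForward()].
#' @examples
#' set.seed(1)
#' blk <- eafBlock(16, 4)
#' x <- array(rnorm(16 * 8 * 8), c(8, 8, 1, 16))
#' dim(moduleForward(blk, x))
#' @export
eafBlock <- function(channels, reduction = 4L) {
  C <- as.integer(channels)
  r <- as.integer(reduction)
  if (r < 1 || C %% r != 0)
    stop("EAF: channels (", C, ") must be divisible by reduction ratio (", r, ")")
  m <- nnModule("eaf")
  m$C <- C
  m$children <- list(
    dw1 = nnDWConv(C, 3L),
    conv1 = nnConv(C, C %/% r, 1L),
    gelu1 = nnGelu(),
    conv2 = nnConv(C %/% r, C, 1L),
    sig = nnSigmoid(),
    fuse = nnConv(2L * C, C, 1L),
    bn1 = nnBN(C),
    gelu2 = nnGelu(),
    dw2 = nnDWConv(C, 3L),
    bn2 = nnBN(C),
    gelu3 = nnGelu())
  m
}

nnForward.nn_eaf <- function(m, x, training = FALSE) {
  ch <- m$children
  s1 <- nnForward(ch$dw1, x, training)
  s2 <- nnForward(ch$sig,
          nnForward(ch$conv2,
            nnForward(ch$gelu1,
              nnForward(ch$conv1, s1, training), training), training), training)
  gated <- x * s2
  s <- nnForward(ch$gelu2,
         nnForward(ch$bn1,
           nnForward(ch$fuse, catChannels(x, gated), training), training),
         training)
  out <- nnForward(ch$gelu3,
           nnForward(ch$bn2, nnForward(ch$dw2, s, training), training),
           training)
  m$cache <- list(x = x, s2 = s2)
  m$lastS2 <- s2
  out
}

nnBackward.nn_eaf <- function(m, dy) {
  ch <- m$children
  cc <- m$cache
  C <- m$C
  ds <- nnBackward(ch$dw2, nnBackward(ch$bn2, nnBackward(ch$gelu3, dy)))
  dcat <- nnBackward(ch$fuse, nnBackward(ch$bn1, nnBackward(ch$gelu2, ds)))
  dx1 <- dcat[, , , seq_len(C), drop = FALSE]
  dgated <- dcat[, , , C + seq_len(C), drop = FALSE]
  dx2 <- dgated * cc$s2
  ds2 <- dgated * cc$x
  dx3 <- nnBackward(ch$dw1,
           nnBackward(ch$conv1,
             nnBackward(ch$gelu1,
               nnBackward(ch$conv2, nnBackward(ch$sig, ds2)))))
  dx1 + dx2 + dx3
}

nnDescribe.nn_eaf <- function(m, shp) {
  C <- m$C
  sC <- c(shp[1], shp[2], C)
  sr <- c(shp[1], shp[2], m$children$conv1$cout)
  rows <- rbind(
    nnDescribe(m$children$dw1, sC)$rows,
    nnDescribe(m$children$conv1, sC)$rows,
    nnDescribe(m$children$conv2, sr)$rows,
    nnDescribe(m$children$fuse, c(shp[1], shp[2], 2L * C))$rows,
    nnDescribe(m$children$bn1, sC)$rows,
    nnDescribe(m$children$dw2, sC)$rows,
    nnDescribe(m$children$bn2, sC)$rows)
  list(rows = rows, out = sC)
}

## ---------------------------------------------------------------------------
## Channel shuffle upsampling block
## ---------------------------------------------------------------------------

#' Channel shuffle upsampling block (CSU)
#'
#' Decoder upsampling stage: bilinear x2 upsampling, a 9x9 depthwise
#' separable convolution (depthwise 9x9 with padding 4, then pointwise 1x1
#' mapping `cin -> cout`), batch normalization, channel shuffle, and ReLU.
#' Output is non-negative with doubled spatial size.
#'
#' @param cin,cout input / output channel counts.
#' @param groups channel shuffle groups; must divide `cout`.
#' @return an internal network module; apply with [moduleForward()].
#' @export
csuBlock <- function(cin, cout, groups = 4L) {
  cin <- as.integer(cin); cout <- as.integer(cout); g <- as.integer(groups)
  if (g < 1 || cout %% g != 0)
    stop("CSU: output channels (", cout, ") must be divisible by shuffle groups (",
         g, ")")
  m <- nnModule("csu")
  m$cin <- cin; m$cout <- cout
  m$children <- list(
    up = nnUpsample2x(),
    dw = nnDWConv(cin, 9L),
    pw = nnConv(cin, cout, 1L),
    bn = nnBN(cout),
    cs = nnShuffle(cout, g),
    relu = nnRelu())
  m
}

nnForward.nn_csu <- function(m, x, training = FALSE) {
  ch <- m$children
  y <- nnForward(ch$up, x, training)
  y <- nnForward(ch$dw, y, training)
  y <- nnForward(ch$pw, y, training)
  y <- nnForward(ch$bn, y, training)
  y <- nnForward(ch$cs, y, training)
  nnForward(ch$relu, y, training)
}

nnBackward.nn_csu <- function(m, dy) {
  ch <- m$children
  dy <- nnBackward(ch$relu, dy)
  dy <- nnBackward(ch$cs, dy)
  dy <- nnBackward(ch$bn, dy)
  dy <- nnBackward(ch$pw, dy)
  dy <- nnBackward(ch$dw, dy)
  nnBackward(ch$up, dy)
}

nnDescribe.nn_csu <- function(m, shp) {
  up <- c(2L * shp[1], 2L * shp[2], shp[3])
  rows <- rbind(nnDescribe(m$children$dw, up)$rows,
                nnDescribe(m$children$pw, up)$rows,
                nnDescribe(m$children$bn, c(up[1], up[2], m$cout))$rows)
  list(rows = rows, out = c(up[1], up[2], m$cout))
}

## ---------------------------------------------------------------------------
## Multi-scale convolution block
## ---------------------------------------------------------------------------

#' Multi-scale convolution block (MCB)
#'
#' Aggregates several receptive-field scales with parallel depthwise
#' separable branches: for each kernel size k, a depthwise kxk convolution
#' followed by its own pointwise 1x1 mapping `cin -> cint`; branch outputs
#' are summed, then BN + GELU. With a single kernel the block reduces to one
#' depthwise separable convolution.
#'
#' @param cin,cint input / intermediate channel counts.
#' @param kernels depthwise kernel sizes (odd, >= 1).
#' @return an internal network module; apply with [moduleForward()].
#' @export
mcbBlock <- function(cin, cint, kernels = c(1L, 3L, 5L)) {
  stopifnot(length(kernels) >= 1, all(kernels %% 2 == 1))
  m <- nnModule("mcb")
  m$cin <- as.integer(cin); m$cint <- as.integer(cint)
  m$kernels <- as.integer(kernels)
  ch <- list()
  for (i in seq_along(kernels)) {
    ch[[paste0("dw", i)]] <- nnDWConv(m$cin, m$kernels[i])
    ch[[paste0("pw", i)]] <- nnConv(m$cin, m$cint, 1L)
  }
  ch$bn <- nnBN(m$cint)
  ch$gelu <- nnGelu()
  m$children <- ch
  m
}

nnForward.nn_mcb <- function(m, x, training = FALSE) {
  ch <- m$children
  s <- NULL
  for (i in seq_along(m$kernels)) {
    b <- nnForward(ch[[paste0("pw", i)]],
                   nnForward(ch[[paste0("dw", i)]], x, training), training)
    s <- if (is.null(s)) b else s + b
  }
  nnForward(ch$gelu, nnForward(ch$bn, s, training), training)
}

nnBackward.nn_mcb <- function(m, dy) {
  ch <- m$children
  ds <- nnBackward(ch$bn, nnBackward(ch$gelu, dy))
  dx <- NULL
  for (i in seq_along(m$kernels)) {
    b <- nnBackward(ch[[paste0("dw", i)]],
                    nnBackward(ch[[paste0("pw", i)]], ds))
    dx <- if (is.null(dx)) b else dx + b
  }
  dx
}

nnDescribe.nn_mcb <- function(m, shp) {
  rows <- NULL
  for (i in seq_along(m$kernels)) {
    rows <- rbind(rows,
                  nnDescribe(m$children[[paste0("dw", i)]], shp)$rows,
                  nnDescribe(m$children[[paste0("pw", i)]], shp)$rows)
  }
  rows <- rbind(rows, nnDescribe(m$children$bn,
                                 c(shp[1], shp[2], m$cint))$rows)
  list(rows = rows, out = c(shp[1], shp[2], m$cint))
}

## ---------------------------------------------------------------------------
## Dual gating
## ---------------------------------------------------------------------------

#' Dual gating (DG)
#'
#' Two parallel 1x1-convolution gates on a fused feature F: a sigmoid gate
#' `A` in (0,1) controlling retention/suppression and a tanh gate `M` in
#' (-1,1) providing signed fine-grained modulation. Branches have
#' independent weights.
#'
#' @param cint channel count of F (and of both gates).
#' @return an internal network module. `moduleForward()` returns
#'   `list(A, M)`.
#' @export
dualGate <- function(cint) {
  m <- nnModule("dg")
  m$cint <- as.integer(cint)
  m$children <- list(
    convA = nnConv(m$cint, m$cint, 1L), sigA = nnSigmoid(),
    convM = nnConv(m$cint, m$cint, 1L), tanhM = nnTanh())
  m
}

nnForward.nn_dg <- function(m, x, training = FALSE) {
  ch <- m$children
  A <- nnForward(ch$sigA, nnForward(ch$convA, x, training), training)
  M <- nnForward(ch$tanhM, nnForward(ch$convM, x, training), training)
  list(A = A, M = M)
}

# dy is list(dA, dM)
nnBackward.nn_dg <- function(m, dy) {
  ch <- m$children
  nnBackward(ch$convA, nnBackward(ch$sigA, dy$dA)) +
    nnBackward(ch$convM, nnBackward(ch$tanhM, dy$dM))
}

nnDescribe.nn_dg <- function(m, shp) {
  rows <- rbind(nnDescribe(m$children$convA, shp)$rows,
                nnDescribe(m$children$convM, shp)$rows)
  list(rows = rows, out = shp)
}

## ---------------------------------------------------------------------------
## Multi-scale spatial attention gated block
## ---------------------------------------------------------------------------

#' Multi-scale spatial attention gated block (MSAG)
#'
#' Combines a global guiding feature `g` (the refined encoder skip) with the
#' local decoder feature `x` at the same spatial size:
#' `fg = MCB(g)`, `fx = MCB(x)`, `F = GELU(BN(Conv1x1(fg + fx)))`,
#' `(A, M) = dual gates on F`, `x_lat = BN(Conv1x1(x))` to `cint` channels,
#' `Y = x_lat * A + x_lat * M` (gated feature transform), and a final
#' pointwise conv + BN maps Y back to the channels of `x`.
#'
#' @param cg,cx channels of g and x.
#' @param cint intermediate channels (defaults to `cx / 2`).
#' @param kernels MCB depthwise kernel sizes.
#' @param useMcb,useDg,useGft component switches for ablations: without MCB
#'   the two multi-scale blocks degrade to plain pointwise projections;
#'   without DG a single sigmoid gate is used; without GFT the gates are not
#'   applied (`Y = x_lat`).
#' @return an internal network module; forward with
#'   `moduleForward(m, list(g = g, x = x))`.
#' @export
msagBlock <- function(cg, cx, cint = NULL, kernels = c(1L, 3L, 5L),
                      useMcb = TRUE, useDg = TRUE, useGft = TRUE) {
  cg <- as.integer(cg); cx <- as.integer(cx)
  if (is.null(cint)) cint <- max(1L, cx %/% 2L)
  cint <- as.integer(cint)
  stopifnot(cint >= 1)
  m <- nnModule("msag")
  m$cg <- cg; m$cx <- cx; m$cint <- cint
  m$useMcb <- isTRUE(useMcb); m$useDg <- isTRUE(useDg)
  m$useGft <- isTRUE(useGft)
  ch <- list()
  if (m$useMcb) {
    ch$mcbG <- mcbBlock(cg, cint, kernels)
    ch$mcbX <- mcbBlock(cx, cint, kernels)
  } else {
    ch$mcbG <- nnSeq(nnConv(cg, cint, 1L))
    ch$mcbX <- nnSeq(nnConv(cx, cint, 1L))
  }
  ch$fuse <- nnConv(cint, cint, 1L)
  ch$bnF <- nnBN(cint)
  ch$geluF <- nnGelu()
  if (m$useDg) {
    ch$gate <- dualGate(cint)
  } else {
    ch$gate <- nnSeq(nnConv(cint, cint, 1L), nnSigmoid())
  }
  ch$convLat <- nnConv(cx, cint, 1L)
  ch$bnLat <- nnBN(cint)
  ch$convOut <- nnConv(cint, cx, 1L)
  ch$bnOut <- nnBN(cx)
  m$children <- ch
  m
}

nnForward.nn_msag <- function(m, x, training = FALSE) {
  g <- x$g; xx <- x$x
  if (!all(dim(g)[1:2] == dim(xx)[1:2]))
    stop("MSAG: g and x must share spatial size")
  ch <- m$children
  xlat <- nnForward(ch$bnLat, nnForward(ch$convLat, xx, training), training)
  if (m$useGft) {
    fg <- nnForward(ch$mcbG, g, training)
    fx <- nnForward(ch$mcbX, xx, training)
    FF <- nnForward(ch$geluF,
            nnForward(ch$bnF, nnForward(ch$fuse, fg + fx, training), training),
            training)
    if (m$useDg) {
      gates <- nnForward(ch$gate, FF, training)
      Y <- xlat * gates$A + xlat * gates$M
      m$lastA <- gates$A
      m$lastM <- gates$M
      m$cache <- list(xlat = xlat, A = gates$A, M = gates$M, mode = "dg")
    } else {
      A <- nnForward(ch$gate, FF, training)
      Y <- xlat * A
      m$lastA <- A
      m$lastM <- NULL
      m$cache <- list(xlat = xlat, A = A, mode = "single")
    }
  } else {
    Y <- xlat
    m$cache <- list(mode = "bypass")
  }
  nnForward(ch$bnOut, nnForward(ch$convOut, Y, training), training)
}

# returns list(dg, dx)
nnBackward.nn_msag <- function(m, dy) {
  ch <- m$children
  cc <- m$cache
  dY <- nnBackward(ch$convOut, nnBackward(ch$bnOut, dy))
  if (cc$mode == "bypass") {
    dxlat <- dY
    dg <- NULL
  } else if (cc$mode == "dg") {
    dxlat <- dY * (cc$A + cc$M)
    dA <- dY * cc$xlat
    dM <- dY * cc$xlat
    dF <- nnBackward(ch$gate, list(dA = dA, dM = dM))
    dsum <- nnBackward(ch$fuse, nnBackward(ch$bnF, nnBackward(ch$geluF, dF)))
    dg <- nnBackward(ch$mcbG, dsum)
    dxlat_extra <- nnBackward(ch$mcbX, dsum)
  } else {
    dxlat <- dY * cc$A
    dA <- dY * cc$xlat
    dF <- nnBackward(ch$gate, dA)
    dsum <- nnBackward(ch$fuse, nnBackward(ch$bnF, nnBackward(ch$geluF, dF)))
    dg <- nnBackward(ch$mcbG, dsum)
    dxlat_extra <- nnBackward(ch$mcbX, dsum)
  }
  dx <- nnBackward(ch$convLat, nnBackward(ch$bnLat, dxlat))
  if (cc$mode != "bypass") dx <- dx + dxlat_extra
  list(dg = dg, dx = dx)  # dg is NULL in bypass mode
}

nnDescribe.nn_msag <- function(m, shp) {
  # shp carries the spatial size; channels differ per input
  sg <- c(shp[1], shp[2], m$cg)
  sx <- c(shp[1], shp[2], m$cx)
  si <- c(shp[1], shp[2], m$cint)
  rows <- rbind(
    nnDescribe(m$children$mcbG, sg)$rows,
    nnDescribe(m$children$mcbX, sx)$rows,
    nnDescribe(m$children$fuse, si)$rows,
    nnDescribe(m$children$bnF, si)$rows,
    nnDescribe(m$children$gate, si)$rows,
    nnDescribe(m$children$convLat, sx)$rows,
    nnDescribe(m$children$bnLat, si)$rows,
    nnDescribe(m$children$convOut, si)$rows,
    nnDescribe(m$children$bnOut, sx)$rows)
  list(rows = rows, out = sx)
}

## ---------------------------------------------------------------------------
## Channel attention modulation block
## ---------------------------------------------------------------------------

#' Channel attention modulation block (CAM)
#'
#' A ConvNeXt-style residual block with squeeze-and-excitation:
#' `y = x + DropPath(gamma * SE(Conv2(GELU(Conv1(GN(DWConv_kxk(x)))))))`,
#' where Conv1 expands `C -> 4C`, Conv2 compresses `4C -> C`, GN is group
#' normalization (8 groups), SE rescales channels by a sigmoid bottleneck on
#' globally pooled features, and `gamma` is a learnable per-channel
#' LayerScale initialized small so the block starts near the identity.
#'
#' @param C channels.
#' @param kernel depthwise kernel size (3, 5 or 7).
#' @param seReduction SE bottleneck reduction.
#' @param gnGroups group-normalization groups.
#' @param layerScaleInit initial LayerScale value.
#' @param dropPathRate stochastic-depth rate.
#' @return an internal network module; apply with [moduleForward()].
#' @export
camBlock <- function(C, kernel = 3L, seReduction = 16L, gnGroups = 8L,
                     layerScaleInit = 1e-6, dropPathRate = 0) {
  C <- as.integer(C)
  stopifnot(kernel %in% c(3L, 5L, 7L))
  m <- nnModule("cam")
  m$C <- C
  m$children <- list(
    dw = nnDWConv(C, as.integer(kernel)),
    gn = nnGN(C, gnGroups),
    conv1 = nnConv(C, 4L * C, 1L),
    gelu = nnGelu(),
    conv2 = nnConv(4L * C, C, 1L),
    se = nnSE(C, seReduction),
    ls = nnLayerScale(C, layerScaleInit),
    dp = nnDropPath(dropPathRate))
  m
}

nnForward.nn_cam <- function(m, x, training = FALSE) {
  ch <- m$children
  b <- nnForward(ch$dw, x, training)
  b <- nnForward(ch$gn, b, training)
  b <- nnForward(ch$conv1, b, training)
  b <- nnForward(ch$gelu, b, training)
  b <- nnForward(ch$conv2, b, training)
  b <- nnForward(ch$se, b, training)
  m$lastSE <- ch$se$cache$s
  b <- nnForward(ch$ls, b, training)
  b <- nnForward(ch$dp, b, training)
  x + b
}

nnBackward.nn_cam <- function(m, dy) {
  ch <- m$children
  db <- nnBackward(ch$dp, dy)
  db <- nnBackward(ch$ls, db)
  db <- nnBackward(ch$se, db)
  db <- nnBackward(ch$conv2, db)
  db <- nnBackward(ch$gelu, db)
  db <- nnBackward(ch$conv1, db)
  db <- nnBackward(ch$gn, db)
  db <- nnBackward(ch$dw, db)
  dy + db
}

nnDescribe.nn_cam <- function(m, shp) {
  s <- c(shp[1], shp[2], m$C)
  s4 <- c(shp[1], shp[2], 4L * m$C)
  rows <- rbind(
    nnDescribe(m$children$dw, s)$rows,
    nnDescribe(m$children$gn, s)$rows,
    nnDescribe(m$children$conv1, s)$rows,
    nnDescribe(m$children$conv2, s4)$rows,
    nnDescribe(m$children$se, s)$rows,
    nnDescribe(m$children$ls, s)$rows)
  list(rows = rows, out = s)
}

## ---------------------------------------------------------------------------
## Branch fusion
## ---------------------------------------------------------------------------

#' Fuse the MSAG and CAM branch outputs
#'
#' The adaptive strategy forms elementwise gate weights
#' `w = sigmoid(Y_msag)` and returns `w * Y_msag + (1 - w) * Y_cam`, an
#' elementwise convex combination of the two branches. `"addition"` and
#' `"multiplication"` are the plain elementwise alternatives. The
#' `"concatenation"` and `"cascade"` strategies involve network modules
#' (a 1x1 compression conv; applying CAM after MSAG) and are handled by the
#' model graph rather than this pure function.
#'
#' @param ymsag,ycam branch outputs of identical shape.
#' @param strategy fusion strategy name.
#' @return fused array of the same shape.
#' @export
sceafFuse <- function(ymsag, ycam, strategy = "gated_weighted_sum") {
  stopifnot(all(dim(ymsag) == dim(ycam)))
  switch(strategy,
    gated_weighted_sum = {
      w <- 1 / (1 + exp(-ymsag))
      w * ymsag + (1 - w) * ycam
    },
    addition = ymsag + ycam,
    multiplication = ymsag * ycam,
    stop("unknown or non-elementwise fusion strategy: ", strategy))
}

#' Run a network block forward
#'
#' Applies a block built by [eafBlock()], [csuBlock()], [mcbBlock()],
#' [dualGate()], [msagBlock()] or [camBlock()] to a batched feature array of
#' dim `(H, W, N, C)` (or `(H, W, C)` / `(H, W)`, which are promoted to a
#' batch of one).
#'
#' @param module the block.
#' @param x input array, or for [msagBlock()] a `list(g =, x =)`.
#' @param training use training-mode statistics (batch norm) and stochastic
#'   regularizers (drop path).
#' @return the block output (same array convention).
#' @export
moduleForward <- function(module, x, training = FALSE) {
  if (is.list(x) && !is.null(x$g)) {
    x$g <- nnBatch(x$g)
    x$x <- nnBatch(x$x)
    return(nnForward(module, x, training))
  }
  nnForward(module, nnBatch(x), training)
}

#' Number of trainable parameters in a block or model
#'
#' @param module a network block or a [SceafModel-class].
#' @return integer count of trainable scalars.
#' @export
parameterCount <- function(module) {
  if (is(module, "SceafModel")) module <- module@net$root
  nnParamCount(module)
}
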