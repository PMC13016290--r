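# Reference convolutional backbone. The encoder of the published architecture
# is an external pluggable component; any encoder producing four stage
# features E1..E4 at H/2, H/4, H/8, H/16 with non-decreasing channels honours
# the same contract.

convBnGelu <- function(cin, cout, k = 3L, stride = 1L) {
  nnSeq(nnConv(cin, cout, k, stride), nnBN(cout), nnGelu())
}

buildBackboneNet <- function(cfg) {
  stopifnot(is(cfg, "BackboneConfig"))
  sc <- cfg@stageChannels
  m <- nnModule("backbone")
  m$cfg <- cfg
  bps <- rep(cfg@blocksPerStage, length.out = 4L)
  ch <- list(stem = convBnGelu(cfg@inChannels, sc[1], 3L, 2L))
  for (i in 1:4) {
    mods <- list()
    if (i > 1) mods[[length(mods) + 1L]] <- convBnGelu(sc[i - 1], sc[i], 3L, 2L)
    for (b in seq_len(bps[i]))
      mods[[length(mods) + 1L]] <- convBnGelu(sc[i], sc[i], 3L, 1L)
    ch[[paste0("stage", i)]] <- nnSeq(mods)
  }
  m$children <- ch
  m
}

nnForward.nn_backbone <- function(m, x, training = FALSE) {
  ch <- m$children
  s <- nnForward(ch$stem, x, training)
  E1 <- nnForward(ch$stage1, s, training)
  E2 <- nnForward(ch$stage2, E1, training)
  E3 <- nnForward(ch$stage3, E2, training)
  E4 <- nnForward(ch$stage4, E3, training)
  list(E1, E2, E3, E4)
}

# dy: list(dE1..dE4); any element may be NULL
nnBackward.nn_backbone <- function(m, dy) {
  ch <- m$children
  acc <- function(a, b) if (is.null(a)) b else if (is.null(b)) a else a + b
  g <- nnBackward(ch$stage4, dy[[4]])
  g <- nnBackward(ch$stage3, acc(g, dy[[3]]))
  g <- nnBackward(ch$stage2, acc(g, dy[[2]]))
  g <- nnBackward(ch$stage1, acc(g, dy[[1]]))
  nnBackward(ch$stem, g)
}

nnDescribe.nn_backbone <- function(m, shp) {
  rows <- NULL
  dd <- nnDescribe(m$children$stem, shp)
  rows <- rbind(rows, dd$rows)
  s <- dd$out
  outs <- vector("list", 4)
  for (i in 1:4) {
    dd <- nnDescribe(m$children[[paste0("stage", i)]], s)
    rows <- rbind(rows, dd$rows)
    s <- dd$out
    outs[[i]] <- s
  }
  list(rows = rows, out = s, stages = outs)
}

checkImageInput <- function(x) {
  d <- dim(x)
  if (length(d) != 4)
    stop("expected a batched feature array with dim (H, W, N, C)")
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0)
    stop("spatial size (", d[1], " x ", d[2],
         ") must be divisible by 16 for the four-stage encoder")
  if (!all(is.finite(x))) stop("input contains non-finite values")
  invisible(d)
}

#' Encode an image into four stage features
#'
#' Runs the hierarchical encoder and returns the four stage features
#' `E1..E4` with spatial sizes `H/2, H/4, H/8, H/16` and the configured
#' channel counts. Deterministic given fixed weights.
#'
#' @param image array of dim `(H, W)`, `(H, W, C)` or batched
#'   `(H, W, N, C)`; H and W must be divisible by 16 and all values finite.
#' @param net a backbone module from [buildBackbone()], or a
#'   [SceafModel-class] whose encoder is used.
#' @return list of four batched feature arrays (the encoder output stages).
#' @examples
#' set.seed(1)
#' net <- buildBackbone(backboneConfig(stageChannels = c(4, 8, 8, 16)))
#' st <- encode(array(0, c(64, 64)), net)
#' sapply(st, function(e) dim(e)[1])  # 32 16 8 4
#' @export
encode <- function(image, net) {
  if (is(net, "SceafModel")) net <- net@net$root$children$backbone
  x <- nnBatch(image)
  checkImageInput(x)
  nnForward(net, x, training = FALSE)
}

#' Build a freshly initialized reference backbone
#'
#' Weights are drawn from the current RNG state (seed with [set.seed()] for
#' reproducibility).
#'
#' @param config a [BackboneConfig-class].
#' @return a backbone network module for [encode()].
#' @export
buildBackbone <- function(config = backboneConfig()) {
  buildBackboneNet(config)
}
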