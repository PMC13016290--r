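# Independent brute-force oracles used to validate the package
# implementations. These deliberately use the most literal formulation
# available (exhaustive enumeration, all-pairs distances) and share no code
# with the implementation paths they check.

# 95th-percentile Hausdorff via exhaustive all-pairs distances on the same
# boundary definition (face-adjacent background neighbour, border = boundary)
oracleHd <- function(pred, gt, percentile = 0.95, spacing = NULL) {
  bnd <- function(mask) {
    d <- dim(mask)
    pts <- which(mask, arr.ind = TRUE)
    keep <- logical(nrow(pts))
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      onb <- FALSE
      for (ax in seq_along(d)) {
        for (s in c(-1, 1)) {
          q <- p
          q[ax] <- q[ax] + s
          if (q[ax] < 1 || q[ax] > d[ax]) { onb <- TRUE; break }
          if (!mask[matrix(q, 1)]) { onb <- TRUE; break }
        }
        if (onb) break
      }
      keep[i] <- onb
    }
    pts[keep, , drop = FALSE]
  }
  A <- bnd(pred != 0)
  B <- bnd(gt != 0)
  if (nrow(A) == 0 || nrow(B) == 0) return(NA_real_)
  if (!is.null(spacing)) {
    A <- sweep(A, 2, spacing, "*")
    B <- sweep(B, 2, spacing, "*")
  }
  dmat <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      dmat[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  d1 <- apply(dmat, 1, min)
  d2 <- apply(dmat, 2, min)
  max(quantile(d1, percentile, names = FALSE),
      quantile(d2, percentile, names = FALSE))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments (tie-aware: uses the actual ranks of |d|)
oracleWilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  ws <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    ws[m + 1] <- sum(rk[signs])
  }
  pLe <- mean(ws <= W + 1e-9)
  pGe <- mean(ws >= W - 1e-9)
  min(1, 2 * min(pLe, pGe))
}

# channel shuffle as literally specified: reshape (groups, C/groups),
# transpose, flatten
oracleShuffle <- function(channels, groups) {
  C <- length(channels)
  m <- matrix(channels, nrow = groups, byrow = TRUE)  # (g, C/g) row-major
  as.vector(m)  # column-major read = transpose-then-flatten
}

randomMask <- function(h, w, pFg = 0.3) {
  matrix(runif(h * w) < pFg, h, w)
}

tinyModelConfig <- function() {
  modelConfig(
    backbone = backboneConfig(stageChannels = c(4L, 8L, 8L, 16L),
                              blocksPerStage = 1L),
    numClasses = 4L,
    decoderChannels = c(8L, 8L, 4L, 4L),
    sceafPlacement = c("D3", "D2"),
    shuffleGroups = 2L,
    eafReduction = 2L)
}

# internal engine handles used by white-box tests
nnForward <- sceafunet:::nnForward
nnBackward <- sceafunet:::nnBackward
nnZeroGrads <- sceafunet:::nnZeroGrads
nnParamRefs <- sceafunet:::nnParamRefs
nnParamCount <- sceafunet:::nnParamCount
nnSeq <- sceafunet:::nnSeq
nnConv <- sceafunet:::nnConv
nnDWConv <- sceafunet:::nnDWConv
nnBN <- sceafunet:::nnBN
nnGelu <- sceafunet:::nnGelu
nnGetState <- sceafunet:::nnGetState
nnSetState <- sceafunet:::nnSetState
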