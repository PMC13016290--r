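#!/usr/bin/env Rscript
# Calibrates the "paper-budget" configuration: searches integer channel
# widths (encoder stages c1..c4, decoder stages d4..d1, backbone depth) so
# that the budget engine reproduces the reference envelope at 224 x 224
# under the 2 x MAC FLOP convention:
#   base totals        ~ 17.07 M params / 9.90 GFLOPs
#   EAF increment      ~ +0.33 M / +0.72 G      (skip modules, all three)
#   CAM increment      ~ +0.06 M (on top of EAF)
#   MSAG increment     ~ +0.04 M (on top of EAF)
#   full totals        ~ 17.52 M / 11.40 G
# The printed per-module FLOP increments for CAM (+0.13 G) and MSAG
# (+0.07 G) are arithmetically incompatible with their parameter increments
# for this block structure at the D3+D2 placement (see the methods
# vignette); they are reported but not used as search targets.
#
# Output: the calibrated integers and the achieved-vs-target table. The
# result is frozen into R/paper_budget.R (.paperBudget).

suppressPackageStartupMessages(library(sceafunet))

mkConfig <- function(sc, bps, dc) {
  modelConfig(
    backbone = backboneConfig(inChannels = 1L, stageChannels = as.integer(sc),
                              blocksPerStage = as.integer(bps)),
    numClasses = 9L,
    decoderChannels = as.integer(dc),
    sceafPlacement = c("D3", "D2"),
    eafReduction = 4L,
    shuffleGroups = 2L)
}

# budget deltas in the Table-4 sense
measure <- function(sc, bps, dc) {
  full <- mkConfig(sc, bps, dc)
  base <- setModules(full, msag = FALSE, cam = FALSE, eaf = FALSE)
  eafOnly <- setModules(full, msag = FALSE, cam = FALSE, eaf = TRUE)
  eafCam <- setModules(full, msag = FALSE, cam = TRUE, eaf = TRUE)
  eafCam@sceafPlacement <- c("D3", "D2")
  eafMsag <- setModules(full, msag = TRUE, cam = FALSE, eaf = TRUE)
  eafMsag@sceafPlacement <- c("D3", "D2")
  b <- lapply(list(base = base, eaf = eafOnly, cam = eafCam,
                   msag = eafMsag, full = full),
              countBudget, inputSize = 224L)
  list(
    baseP = b$base@totalParams, baseF = b$base@totalFlops,
    eafP = b$eaf@totalParams - b$base@totalParams,
    eafF = b$eaf@totalFlops - b$base@totalFlops,
    camP = b$cam@totalParams - b$eaf@totalParams,
    camF = b$cam@totalFlops - b$eaf@totalFlops,
    msagP = b$msag@totalParams - b$eaf@totalParams,
    msagF = b$msag@totalFlops - b$eaf@totalFlops,
    fullP = b$full@totalParams, fullF = b$full@totalFlops)
}

targets <- c(baseP = 17.07e6, baseF = 9.90e9, eafP = 0.33e6, eafF = 0.72e9,
             camP = 0.06e6, msagP = 0.04e6, fullP = 17.52e6, fullF = 11.40e9)

score <- function(m) {
  rel <- c(baseP = (m$baseP - targets["baseP"]) / targets["baseP"],
           baseF = (m$baseF - targets["baseF"]) / targets["baseF"],
           eafP = (m$eafP - targets["eafP"]) / targets["eafP"],
           eafF = (m$eafF - targets["eafF"]) / targets["eafF"],
           camP = (m$camP - targets["camP"]) / targets["camP"],
           msagP = (m$msagP - targets["msagP"]) / targets["msagP"],
           fullP = (m$fullP - targets["fullP"]) / targets["fullP"],
           fullF = (m$fullF - targets["fullF"]) / targets["fullF"])
  max(abs(rel))
}

## ---- stage 1: EAF channels (c1, c2, c3), multiples of 4 --------------------
# analytic: params(C) = 2.5 C^2 + 26.25 C summed over skips;
# flops(C) = 2 * S^2 * (2.5 C^2 + 18 C), S = 112, 56, 28
eafP <- function(C) 2.5 * C^2 + 26.25 * C
eafF <- function(C, S) 2 * S^2 * (2.5 * C^2 + 18 * C)
best1 <- NULL
for (c1 in seq(8, 80, 4)) {
  for (c2 in seq(c1, 320, 4)) {
    # solve c3 from the parameter target, then check the FLOP target
    rest <- 0.33e6 - eafP(c1) - eafP(c2)
    if (rest < eafP(c2)) next
    c3 <- 4 * round(sqrt(rest / 2.5) / 4)
    if (c3 < c2) next
    p <- eafP(c1) + eafP(c2) + eafP(c3)
    f <- eafF(c1, 112) + eafF(c2, 56) + eafF(c3, 28)
    err <- max(abs(p / 0.33e6 - 1), abs(f / 0.72e9 - 1))
    if (is.null(best1) || err < best1$err)
      best1 <- list(c1 = c1, c2 = c2, c3 = c3, err = err)
  }
}
cat(sprintf("stage 1 (EAF): c1..c3 = %d %d %d (err %.3f)\n",
            best1$c1, best1$c2, best1$c3, best1$err))

## ---- stage 2: decoder widths at D3 / D2 for CAM and MSAG params ------------
camPfun <- function(C) {
  cr <- max(1, C %/% 16)
  (9 * C + C) + 2 * C + (4 * C^2 + 4 * C) + (4 * C^2 + C) +
    (2 * C * cr + cr + C) + C
}
msagPfun <- function(Cg, Cx) {
  Ci <- max(1, round(Cx / 2))
  mcb <- function(cin) sum(c(1, 9, 25) * cin + cin) + 3 * (cin * Ci + Ci) + 2 * Ci
  mcb(Cg) + mcb(Cx) + (Ci^2 + Ci) + 2 * Ci + 2 * (Ci^2 + Ci) +
    (Cx * Ci + Ci) + 2 * Ci + (Ci * Cx + Cx) + 2 * Cx
}
# FLOPs (2 x MAC): CAM per pixel ~ 8 C^2 + 9 C; MSAG per pixel from its
# separable branches, gates and projections
camFfun <- function(C, S) 2 * S^2 * (8 * C^2 + 9 * C)
msagFfun <- function(Cg, Cx, S) {
  Ci <- max(1, round(Cx / 2))
  2 * S^2 * (35 * (Cg + Cx) + 3 * Ci * (Cg + Cx) + 3 * Ci^2 + 2 * Cx * Ci)
}
# among width pairs whose parameter increments match the printed figures
# (within the printed precision + 2%), pick the FLOP-cheapest: the printed
# full-model total implies the CAM+MSAG pair must stay light, which favours
# a narrow D2 (112^2) and a wider D3 (56^2)
best2 <- NULL
for (d3 in seq(16, 120, 2)) {
  for (d2 in seq(8, d3, 2)) {
    cp <- camPfun(d3) + camPfun(d2)
    mp <- msagPfun(best1$c2, d3) + msagPfun(best1$c1, d2)
    perr <- max(abs(cp - 0.06e6) / (0.02 * 0.06e6 + 0.005e6),
                abs(mp - 0.04e6) / (0.02 * 0.04e6 + 0.005e6))
    fl <- camFfun(d3, 56) + camFfun(d2, 112) +
      msagFfun(best1$c2, d3, 56) + msagFfun(best1$c1, d2, 112)
    feasible <- perr <= 0.9
    key <- if (feasible) fl else Inf
    if (is.null(best2) || (feasible && key < best2$key) ||
        (!best2$feasible && perr < best2$perr)) {
      best2 <- list(d3 = d3, d2 = d2, perr = perr, key = key,
                    feasible = feasible, fl = fl)
    }
  }
}
cat(sprintf("stage 2 (CAM/MSAG): d3 = %d d2 = %d (param err %.3f, %.3f G)\n",
            best2$d3, best2$d2, best2$perr, best2$fl / 1e9))

## ---- stage 3: backbone depth/width + remaining decoder widths --------------
# the module increments are structurally additive and fixed by stages 1-2,
# so this stage only needs to hit the BASE totals
# achieved EAF increments (fixed by stage 1)
eafFach <- eafF(best1$c1, 112) + eafF(best1$c2, 56) + eafF(best1$c3, 28)
band <- function(x) 0.02 * x + 0.005e9 * (x > 1e8) + 0.005e6 * (x <= 1e8)
baseErr <- function(sc, bps, dc) {
  base <- setModules(mkConfig(sc, bps, dc), msag = FALSE, cam = FALSE,
                     eaf = FALSE)
  b <- countBudget(base, 224L)
  fullF <- b@totalFlops + eafFach + best2$fl
  max(abs(b@totalParams - targets["baseP"]) / band(targets["baseP"]),
      abs(b@totalFlops - targets["baseF"]) / band(targets["baseF"]),
      abs(fullF - targets["fullF"]) / band(targets["fullF"]))
}
basePF <- function(sc, bps, dc) {
  base <- setModules(mkConfig(sc, bps, dc), msag = FALSE, cam = FALSE,
                     eaf = FALSE)
  b <- countBudget(base, 224L)
  c(P = b@totalParams, F = b@totalFlops)
}
best3 <- NULL
for (b2 in 1:2) for (b3 in 1:2) {
  for (d4 in c(64, 96, 128)) for (d1 in c(8, 16, 32)) {
    for (c4 in seq(max(best1$c3, 344), 960, 16)) {
      sc <- c(best1$c1, best1$c2, best1$c3, c4)
      dc <- c(d4, best2$d3, best2$d2, d1)
      pf1 <- tryCatch(basePF(sc, c(2L, b2, b3, 1L), dc),
                      error = function(e) NULL)
      if (is.null(pf1)) next
      # extra stage-4 blocks add params/FLOPs linearly; pick the depth
      # that best closes the parameter gap, then verify with the engine
      perBlock <- 9 * c4^2 + 2 * c4 + c4  # conv + BN(+bias) params
      b4 <- max(1L, 1L + as.integer(round((targets["baseP"] - pf1["P"]) /
                                            perBlock)))
      for (b4try in unique(pmax(1L, b4 + (-1:1)))) {
        bps <- c(2L, b2, b3, b4try)
        e <- tryCatch(baseErr(sc, bps, dc), error = function(e) NA)
        if (is.na(e)) next
        if (is.null(best3) || e < best3$e)
          best3 <- list(sc = sc, bps = bps, dc = dc, e = e)
      }
    }
  }
  cat(sprintf("  after b2 = %d b3 = %d: best base err %.4f\n",
              b2, b3, best3$e))
}
# local refinement around the best coarse solution
repeat {
  improved <- FALSE
  for (dc4 in c(-8, -4, 4, 8)) for (dd4 in c(-16, 0, 16)) for (dd1 in c(-8, 0, 8)) {
    sc <- best3$sc; sc[4] <- sc[4] + dc4
    dc <- best3$dc; dc[1] <- dc[1] + dd4; dc[4] <- dc[4] + dd1
    if (sc[4] < sc[3] || any(dc < 4) || dc[1] < dc[2]) next
    e <- tryCatch(baseErr(sc, best3$bps, dc), error = function(e) NA)
    if (!is.na(e) && e < best3$e) {
      best3 <- list(sc = sc, bps = best3$bps, dc = dc, e = e)
      improved <- TRUE
    }
  }
  if (!improved) break
}
best3$m <- measure(best3$sc, best3$bps, best3$dc)
best3$s <- score(best3$m)
cat(sprintf("refined: base err %.4f, overall target score %.4f\n",
            best3$e, best3$s))

cat("\ncalibrated configuration:\n")
cat("  stageChannels:", best3$sc, " blocksPerStage:", best3$bps, "\n")
cat("  decoderChannels:", best3$dc, "\n\n")
m <- best3$m
tab <- data.frame(
  quantity = c("base params (M)", "base FLOPs (G)", "EAF dP (M)",
               "EAF dF (G)", "CAM dP (M)", "CAM dF (G)", "MSAG dP (M)",
               "MSAG dF (G)", "full params (M)", "full FLOPs (G)"),
  achieved = c(m$baseP / 1e6, m$baseF / 1e9, m$eafP / 1e6, m$eafF / 1e9,
               m$camP / 1e6, m$camF / 1e9, m$msagP / 1e6, m$msagF / 1e9,
               m$fullP / 1e6, m$fullF / 1e9),
  printed = c(17.07, 9.90, 0.33, 0.72, 0.06, 0.13, 0.04, 0.07,
              17.52, 11.40))
tab$relErr <- tab$achieved / tab$printed - 1
print(tab, digits = 4)

cat("\n.paperBudget <- list(\n")
cat(sprintf("  stageChannels = c(%s),\n",
            paste0(best3$sc, "L", collapse = ", ")))
cat(sprintf("  blocksPerStage = c(%s),\n",
            paste0(rep(best3$bps, length.out = 4), "L", collapse = ", ")))
cat(sprintf("  decoderChannels = c(%s),\n",
            paste0(best3$dc, "L", collapse = ", ")))
cat("  shuffleGroups = 2L)\n")
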