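# Decoder blocks: channel-shuffle upsampling, multi-scale convolution,
# dual gating, MSAG, CAM and the branch fusion strategies.

test_that("channel shuffle is the reshape-transpose-flatten permutation", {
  expect_equal(channelShufflePerm(4, 2), oracleShuffle(1:4, 2))
  # on 0-based channel ids (0,1,2,3) with g = 2 the order becomes (0,2,1,3)
  expect_equal(channelShufflePerm(4, 2) - 1L, c(0L, 2L, 1L, 3L))
  for (C in c(6, 8, 12)) for (g in c(2, 3)) {
    if (C %% g != 0) next
    p <- channelShufflePerm(C, g)
    expect_equal(p, oracleShuffle(seq_len(C), g))
    expect_setequal(p, seq_len(C))           # a permutation
    expect_equal(p[order(p)], seq_len(C))    # inverse recovers identity
  }
})

test_that("CSU doubles spatial size, is non-negative, and validates groups", {
  set.seed(11)
  blk <- csuBlock(8, 4, 2)
  x <- array(rnorm(16 * 16 * 1 * 8), c(16, 16, 1, 8))
  y <- moduleForward(blk, x, training = TRUE)
  expect_equal(dim(y), c(32L, 32L, 1L, 4L))
  expect_true(all(y >= 0))
  expect_error(csuBlock(8, 6, 4), "divisible")

  # the shuffle inside is a pure permutation: applying the inverse
  # permutation recovers the pre-shuffle channels exactly
  z <- array(rnorm(4 * 4 * 1 * 6), c(4, 4, 1, 6))
  p <- channelShufflePerm(6, 3)
  shuffled <- z[, , , p, drop = FALSE]
  expect_identical(shuffled[, , , order(p), drop = FALSE], z)
})

test_that("MCB honours the channel contract and zero fixed point", {
  set.seed(12)
  blk <- mcbBlock(16, 8)
  x <- array(rnorm(8 * 8 * 1 * 16), c(8, 8, 1, 16))
  y <- moduleForward(blk, x)
  expect_equal(dim(y), c(8L, 8L, 1L, 8L))
  expect_true(all(moduleForward(blk, array(0, dim(x))) == 0))
})

test_that("single-kernel MCB equals a directly built separable conv", {
  set.seed(13)
  blk <- mcbBlock(6, 4, kernels = 3L)
  x <- array(rnorm(8 * 8 * 2 * 6), c(8, 8, 2, 6))
  y <- moduleForward(blk, x)
  # independent single-branch module with copied weights
  ref <- nnSeq(nnDWConv(6, 3L), nnConv(6, 4, 1L), nnBN(4), nnGelu())
  ref$children[[1]]$params <- blk$children$dw1$params
  ref$children[[2]]$params <- blk$children$pw1$params
  ref$children[[3]]$params <- blk$children$bn$params
  ref$children[[3]]$buffers <- blk$children$bn$buffers
  expect_equal(moduleForward(ref, x), y, tolerance = 1e-12)
})

test_that("dual gates obey their codomains and the zero-input fixed values", {
  set.seed(14)
  dg <- dualGate(6)
  z <- array(0, c(5, 5, 1, 6))
  g0 <- moduleForward(dg, z)
  expect_true(all(g0$A == 0.5))   # sigmoid(0)
  expect_true(all(g0$M == 0))     # tanh(0)

  x <- array(rnorm(10 * 10 * 4 * 6), c(10, 10, 4, 6))
  g <- moduleForward(dg, x)
  expect_true(min(g$A) > 0 && max(g$A) < 1)
  expect_true(all(abs(g$M) < 1))
})

test_that("MSAG output matches the channel contract and gate bounds", {
  set.seed(15)
  blk <- msagBlock(32, 16, 8)
  g <- array(rnorm(8 * 8 * 2 * 32), c(8, 8, 2, 32))
  x <- array(rnorm(8 * 8 * 2 * 16), c(8, 8, 2, 16))
  y <- moduleForward(blk, list(g = g, x = x), training = TRUE)
  expect_equal(dim(y), c(8L, 8L, 2L, 16L))
  expect_true(all(blk$lastA > 0 & blk$lastA < 1))
  expect_true(all(abs(blk$lastM) < 1))
  expect_error(moduleForward(blk, list(g = g[1:4, 1:4, , , drop = FALSE],
                                       x = x)),
               "spatial")
})

test_that("Y = x_lat (A + M) is bounded by 2 |x_lat| and gates bypass", {
  set.seed(16)
  blk <- msagBlock(8, 8, 4)
  g <- array(rnorm(6 * 6 * 1 * 8), c(6, 6, 1, 8))
  x <- array(rnorm(6 * 6 * 1 * 8), c(6, 6, 1, 8))
  invisible(moduleForward(blk, list(g = g, x = x), training = TRUE))
  cc <- blk$cache
  Y <- cc$xlat * cc$A + cc$xlat * cc$M
  expect_true(all(abs(Y) <= 2 * abs(cc$xlat) + 1e-12))

  # force A ~= 1 (large positive gate bias) and M = 0 (zero tanh weights):
  # the block reduces to BN(Conv1x1(x_lat)), the gate-bypass identity
  blk$children$gate$children$convA$params$W[] <- 0
  blk$children$gate$children$convA$params$b[] <- 30   # sigmoid -> ~1
  blk$children$gate$children$convM$params$W[] <- 0
  blk$children$gate$children$convM$params$b[] <- 0    # tanh -> 0
  y <- moduleForward(blk, list(g = g, x = x), training = TRUE)
  xlat <- blk$cache$xlat
  ref <- nnForward(blk$children$bnOut,
                   nnForward(blk$children$convOut, xlat, TRUE), TRUE)
  expect_equal(y, ref, tolerance = 1e-7)
})

test_that("CAM with zero LayerScale is the exact identity", {
  set.seed(17)
  blk <- camBlock(8, 3, layerScaleInit = 0)
  x <- array(rnorm(8 * 8 * 2 * 8), c(8, 8, 2, 8))
  expect_identical(moduleForward(blk, x, training = FALSE), x)
})

test_that("CAM drop path with rate 1 passes the input through in training", {
  set.seed(18)
  blk <- camBlock(8, 3, layerScaleInit = 0.5, dropPathRate = 1)
  x <- array(rnorm(6 * 6 * 2 * 8), c(6, 6, 2, 8))
  expect_equal(moduleForward(blk, x, training = TRUE), x)
})

test_that("CAM SE scale lies in (0,1) and eval mode is deterministic", {
  set.seed(19)
  blk <- camBlock(8, 5, seReduction = 4, layerScaleInit = 1e-2)
  x <- array(rnorm(8 * 8 * 3 * 8, sd = 2), c(8, 8, 3, 8))
  y1 <- moduleForward(blk, x, training = TRUE)   # populate BN-free caches
  s <- blk$lastSE
  expect_true(all(s > 0 & s < 1))
  e1 <- moduleForward(blk, x, training = FALSE)
  e2 <- moduleForward(blk, x, training = FALSE)
  expect_identical(e1, e2)
})

test_that("fusion strategies match their elementwise definitions", {
  set.seed(20)
  ym <- array(rnorm(200), c(5, 5, 2, 4))
  yc <- array(rnorm(200), c(5, 5, 2, 4))

  got <- sceafFuse(ym, yc, "gated_weighted_sum")
  w <- 1 / (1 + exp(-ym))
  expect_equal(got, w * ym + (1 - w) * yc)
  # convex combination: bounded by branch extrema everywhere
  expect_true(all(got >= pmin(ym, yc) - 1e-12 & got <= pmax(ym, yc) + 1e-12))

  expect_equal(sceafFuse(ym, yc, "addition"), ym + yc)
  expect_equal(sceafFuse(ym, yc, "multiplication"), ym * yc)
  expect_error(sceafFuse(ym, yc, "frobnicate"), "unknown")

  # zero MSAG branch: weight is exactly 1/2
  z <- array(0, dim(yc))
  expect_equal(sceafFuse(z, yc), 0.5 * yc)

  # scalar evaluation: Ym = +10, Yc = 0 -> 10 * sigmoid(10) per element
  t10 <- array(10, c(2, 2, 1, 1))
  expect_equal(sceafFuse(t10, 0 * t10)[1], 10 / (1 + exp(-10)),
               tolerance = 1e-12)
  expect_equal(sceafFuse(t10, 0 * t10)[1], 9.99954602, tolerance = 1e-7)
})

test_that("gate codomains hold over a large random sweep", {
  set.seed(21)
  dg <- dualGate(4)
  eaf <- eafBlock(4, 2)
  n <- 0
  while (n < 1e4) {
    x <- array(rnorm(10 * 10 * 3 * 4), c(10, 10, 3, 4))
    gg <- moduleForward(dg, x)
    expect_true(all(gg$A > 0 & gg$A < 1))
    expect_true(all(gg$M > -1 & gg$M < 1))
    invisible(moduleForward(eaf, x, training = TRUE))
    expect_true(all(eaf$lastS2 > 0 & eaf$lastS2 < 1))
    n <- n + length(gg$A)
  }
})
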