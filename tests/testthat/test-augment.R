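# Online augmentation, preprocessing and test-time augmentation.

test_that("rot90/flip branch preserves per-class pixel counts exactly", {
  set.seed(61)
  pol <- augmentPolicy(pGeo = 1)  # force the permutation branch
  img <- matrix(runif(64 * 64), 64, 64)
  lab <- matrix(sample(0:3, 64 * 64, TRUE), 64, 64)
  for (i in 1:10) {
    out <- augmentSample(img, lab, pol)
    expect_equal(out$branch, "geo")
    expect_equal(tabulate(out$label + 1L, 4), tabulate(lab + 1L, 4))
    expect_equal(sort(as.vector(out$image)), sort(as.vector(img)))
  }
})

test_that("augmentation is deterministic under a fixed seed", {
  img <- matrix(runif(32 * 32), 32, 32)
  lab <- matrix(sample(0:2, 32 * 32, TRUE), 32, 32)
  set.seed(62)
  a <- augmentSample(img, lab)
  set.seed(62)
  b <- augmentSample(img, lab)
  expect_identical(a, b)
})

test_that("image and label receive identical geometry", {
  # encode coordinates in the image; wherever a label lands, the image
  # value must be the one originating from the same source pixel
  S <- 32
  coords <- matrix(seq_len(S * S), S, S)
  lab <- coords %% 7
  set.seed(63)
  for (i in 1:20) {
    out <- augmentSample(coords, lab, augmentPolicy(pGeo = 1))
    expect_equal(out$label, out$image %% 7)
  }
})

test_that("branch frequencies match (0.5, 0.125, 0.375) within 3 sigma", {
  set.seed(64)
  img <- matrix(0, 16, 16)
  lab <- matrix(0L, 16, 16)
  n <- 10000
  branches <- character(n)
  for (i in seq_len(n)) branches[i] <- augmentSample(img, lab)$branch
  tab <- table(factor(branches, c("geo", "smallrot", "identity"))) / n
  for (probe in list(c("geo", 0.5), c("smallrot", 0.125),
                     c("identity", 0.375))) {
    p <- as.numeric(probe[2])
    sigma <- sqrt(p * (1 - p) / n)
    expect_lt(abs(tab[[probe[1]]] - p), 3 * sigma)
  }
})

test_that("small rotations keep the label set and stay in range", {
  set.seed(65)
  pol <- augmentPolicy(pGeo = 0, pSmallRot = 1)
  img <- matrix(runif(48 * 48), 48, 48)
  lab <- matrix(sample(0:3, 48 * 48, TRUE), 48, 48)
  out <- augmentSample(img, lab, pol)
  expect_equal(out$branch, "smallrot")
  expect_true(all(out$label %in% 0:3))
  expect_equal(dim(out$image), dim(img))
})

test_that("label resize never introduces new class ids", {
  set.seed(66)
  lab <- array(sample(c(0L, 2L, 5L), 24 * 24 * 3, TRUE,
                      prob = c(0.7, 0.2, 0.1)), c(24, 24, 3))
  img <- array(runif(24 * 24 * 3), c(24, 24, 3))
  for (m in c("bicubic", "nearest")) {
    out <- preprocessVolume(img, lab, 32L, m)
    for (s in out) expect_true(all(s$label %in% c(0L, 2L, 5L)))
  }
})

test_that("constant images resize to the same constant", {
  img <- array(0.37, c(16, 16, 2))
  lab <- array(0L, c(16, 16, 2))
  out <- preprocessVolume(img, lab, 48L, "bicubic")
  for (s in out) expect_equal(max(abs(s$image - 0.37)), 0, tolerance = 1e-12)
})

test_that("nearest upsampling of a 2x2 checkerboard gives exact blocks", {
  img <- matrix(c(1, 0, 0, 1), 2, 2)
  lab <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  out <- preprocessVolume(img, lab, 4L, "nearest")[[1]]
  ref <- matrix(c(1, 1, 0, 0,
                  1, 1, 0, 0,
                  0, 0, 1, 1,
                  0, 0, 1, 1), 4, 4)
  expect_equal(out$image, ref)
  expect_equal(out$label, matrix(as.integer(ref), 4, 4))
  expect_error(preprocessVolume(array(0, c(4, 4, 2)), array(0L, c(4, 4, 3))),
               "differ")
})

test_that("TTA uses the documented transform counts and keeps the simplex", {
  expect_length(sceafunet:::ttaTransforms("flip"), 2L)
  expect_length(sceafunet:::ttaTransforms("flip_rot90"), 8L)

  set.seed(67)
  m <- buildModel(tinyModelConfig())
  img <- matrix(rnorm(32 * 32), 32, 32)
  for (mode in c("flip", "flip_rot90")) {
    pr <- ttaPredict(m, img, mode)
    sums <- apply(pr, c(1, 2), sum)
    expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-6)
    expect_true(all(pr >= 0))
  }
})

test_that("flip TTA equals a hand-assembled transform average", {
  set.seed(68)
  m <- buildModel(tinyModelConfig())
  img <- matrix(rnorm(32 * 32), 32, 32)
  p1 <- predictSegmentation(m, img, tta = "none")$probs
  flipped <- img[, 32:1]
  p2raw <- predictSegmentation(m, flipped, tta = "none")$probs
  p2 <- p2raw[, 32:1, ]                      # invert the flip per channel
  manual <- (p1 + p2) / 2
  expect_equal(ttaPredict(m, img, "flip"), manual, tolerance = 1e-12)
})
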