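# Training protocol: loss arithmetic, schedule endpoints, optimization on a
# learnable toy problem, reproducibility.

test_that("hybrid loss with beta = 0 equals hand-computed cross-entropy", {
  # 2x2 single image, 2 classes, hand log-softmax arithmetic
  z <- array(0, c(2, 2, 2))
  z[, , 1] <- matrix(c(2, 0, 1, -1), 2, 2)
  z[, , 2] <- matrix(c(0, 1, -1, 3), 2, 2)
  lab <- matrix(c(0L, 1L, 0L, 1L), 2, 2)
  byHand <- -mean(c(
    2 - log(exp(2) + exp(0)),
    1 - log(exp(0) + exp(1)),
    1 - log(exp(1) + exp(-1)),
    3 - log(exp(-1) + exp(3))))
  got <- hybridLoss(z, lab, alpha = 1, beta = 0)
  expect_equal(got$loss, byHand, tolerance = 1e-12)
  expect_equal(got$ce, byHand, tolerance = 1e-12)
})

test_that("hybrid loss is the stated linear combination of its parts", {
  set.seed(71)
  z <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  lab <- matrix(sample(0:2, 64, TRUE), 8, 8)
  l1 <- hybridLoss(z, lab, 1, 0)
  l2 <- hybridLoss(z, lab, 0, 1)
  l3 <- hybridLoss(z, lab, 0.5, 0.5)
  expect_equal(l3$loss, 0.5 * l1$loss + 0.5 * l2$loss, tolerance = 1e-12)
  expect_gte(l3$loss, 0)
})

test_that("loss vanishes as a correct prediction grows confident", {
  lab <- matrix(sample(0:1, 36, TRUE), 6, 6)
  mkLogits <- function(scale) {
    z <- array(0, c(6, 6, 2))
    z[, , 1] <- scale * (lab == 0)
    z[, , 2] <- scale * (lab == 1)
    z
  }
  l10 <- hybridLoss(mkLogits(10), lab)$loss
  l40 <- hybridLoss(mkLogits(40), lab)$loss
  expect_lt(l40, l10)
  expect_lt(l40, 1e-4)
})

test_that("out-of-range labels raise an error", {
  z <- array(0, c(4, 4, 3))
  expect_error(hybridLoss(z, matrix(3L, 4, 4)), "0..K-1")
  expect_error(hybridLoss(z, matrix(-1L, 4, 4)), "0..K-1")
})

test_that("loss gradient matches finite differences", {
  set.seed(72)
  z <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  lab <- array(sample(0:2, 32, TRUE), c(4, 4, 2))
  g <- hybridLoss(z, lab, 0.4, 0.6, grad = TRUE)$grad
  for (i in sample(length(z), 6)) {
    zp <- z; zp[i] <- zp[i] + 1e-6
    zm <- z; zm[i] <- zm[i] - 1e-6
    num <- (hybridLoss(zp, lab, 0.4, 0.6)$loss -
            hybridLoss(zm, lab, 0.4, 0.6)$loss) / 2e-6
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("cosine schedule hits its endpoints and midpoint exactly", {
  expect_equal(cosineLr(30, 30, 1e-3, 0), 0)
  expect_equal(cosineLr(15, 30, 1e-3, 0), 5e-4)
  expect_equal(cosineLr(10, 20, 2e-3, 4e-4), (2e-3 + 4e-4) / 2)
  lrs <- sapply(1:30, cosineLr, epochs = 30, baseLr = 1e-3, minLr = 0)
  expect_true(all(diff(lrs) < 0))
})

test_that("training reduces the loss on a learnable toy problem", {
  spec <- syntheticSpec(imageSize = 32L, nTrain = 36, nVal = 4, nTest = 4,
                        seed = 99L)
  data <- generateDataset(spec)
  cfg <- tinyModelConfig()
  tc <- trainConfig(epochs = 10L, baseLr = 5e-3, batchSize = 12L,
                    seed = 321L, inputSize = 32L, augment = FALSE)
  fit <- runTraining(cfg, tc, data = data)
  h <- fit$history
  expect_equal(nrow(h), 10)
  expect_lt(tail(h$loss, 1), h$loss[1] * 0.8)
  expect_true(all(is.finite(h$loss)))
  expect_equal(h$lr[10], 0)
})

test_that("two runs with the same seed are bitwise identical", {
  spec <- syntheticSpec(imageSize = 32L, nTrain = 12, nVal = 2, nTest = 2,
                        seed = 7L)
  data <- generateDataset(spec)
  cfg <- tinyModelConfig()
  tc <- trainConfig(epochs = 2L, baseLr = 1e-3, batchSize = 6L,
                    seed = 1234L, inputSize = 32L, augment = TRUE)
  f1 <- runTraining(cfg, tc, data = data)
  f2 <- runTraining(cfg, tc, data = data)
  expect_identical(f1$history, f2$history)
  expect_identical(nnGetState(f1$model@net$root),
                   nnGetState(f2$model@net$root))
})

test_that("checkpoints round-trip weights and reproduce predictions", {
  set.seed(73)
  m <- buildModel(tinyModelConfig())
  img <- matrix(rnorm(32 * 32), 32, 32)
  p1 <- predictSegmentation(m, img)$probs
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(m, f, extra = list(tag = "unit"))
  back <- loadCheckpoint(f)
  expect_equal(back$extra$tag, "unit")
  expect_identical(predictSegmentation(back$model, img)$probs, p1)
  unlink(f)
})

test_that("non-finite losses abort with diagnostics", {
  spec <- syntheticSpec(imageSize = 32L, nTrain = 6, nVal = 1, nTest = 1)
  data <- generateDataset(spec)
  set.seed(74)
  m <- buildModel(tinyModelConfig())
  # poison the head weights so the forward pass produces NaN logits
  m@net$root$children$head$params$W[] <- NaN
  tc <- trainConfig(epochs = 1L, batchSize = 6L, inputSize = 32L,
                    seed = 1L, augment = FALSE)
  expect_error(trainModel(m, data, tc), "label|finite|loss")
})
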