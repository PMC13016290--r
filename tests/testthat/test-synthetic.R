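# Synthetic phantom generator: determinism, noiseless construction,
# rasterization accuracy, learnability margin, fixture round-trips.

test_that("identical seeds regenerate identical cases", {
  spec <- syntheticSpec(nTrain = 2, nVal = 1, nTest = 1)
  a <- generateCase(spec, 7)
  b <- generateCase(spec, 7)
  expect_identical(a$image, b$image)
  expect_identical(a$label, b$label)
  c <- generateCase(spec, 8)
  expect_false(identical(a$label, c$label))
})

test_that("zero noise yields a piecewise-constant image with K values", {
  spec <- syntheticSpec(noiseSd = 0)
  cs <- generateCase(spec, 3)
  present <- sort(unique(as.vector(cs$label)))
  expect_equal(length(unique(as.vector(cs$image))), length(present))
  # each class region is exactly constant
  for (k in present)
    expect_equal(length(unique(cs$image[cs$label == k])), 1L)
})

test_that("class regions are disjoint and labels lie in 0..K-1", {
  spec <- syntheticSpec()
  for (i in 1:10) {
    cs <- generateCase(spec, 100 + i)
    expect_true(all(cs$label %in% 0:3))
  }
})

test_that("foreground classes are present in nearly all cases", {
  spec <- syntheticSpec()
  n <- 200
  present <- matrix(FALSE, n, 3)
  for (i in seq_len(n)) {
    cs <- generateCase(spec, 1000 + i)
    present[i, ] <- vapply(1:3, function(k) any(cs$label == k), TRUE)
  }
  # dropout probability is 0.05 per small structure; demand >= 0.9 presence
  expect_true(all(colMeans(present) >= 0.9))
})

test_that("ring pixel count matches the analytic annulus area", {
  # rasterization error of a disc boundary is bounded by its perimeter
  spec <- syntheticSpec(noiseSd = 0)
  checked <- 0
  for (i in 1:30) {
    cs <- generateCase(spec, 2000 + i)
    npix <- sum(cs$label == 2)
    if (npix == 0) next
    # recover the drawn annulus parameters by regenerating the geometry:
    # area pi (R^2 - r^2) with R <= 0.18 * 64, thickness <= 4
    # bound check: area of the widest admissible annulus
    Rmax <- 0.18 * spec@imageSize
    areaMax <- pi * (Rmax^2 - (Rmax - 4)^2) + 2 * pi * Rmax
    areaMin <- pi * (0.10 * spec@imageSize * 2 * 1) / 2  # thinnest ring
    expect_lt(npix, areaMax)
    expect_gt(npix, 2)
    checked <- checked + 1
  }
  expect_gt(checked, 20)
})

test_that("class mean intensities keep a 2-noise-sd learnability margin", {
  spec <- syntheticSpec()
  for (i in 1:20) {
    cs <- generateCase(spec, 3000 + i)
    expect_true(all(diff(cs$means) >= 2 * spec@noiseSd))
    expect_true(all(cs$image >= 0 & cs$image <= 1))
  }
  # spec validity rejects an unlearnable configuration
  expect_error(syntheticSpec(noiseSd = 0.2), "2 \\* noiseSd")
})

test_that("ring thickness distribution spans thin walls", {
  spec <- syntheticSpec(noiseSd = 0)
  thick <- c()
  for (i in 1:60) {
    cs <- generateCase(spec, 4000 + i)
    if (!any(cs$label == 2)) next
    # estimate wall thickness from area / mean circumference
    pts <- which(cs$label == 2, arr.ind = TRUE)
    cy <- mean(pts[, 1]); cx <- mean(pts[, 2])
    rr <- sqrt((pts[, 1] - cy)^2 + (pts[, 2] - cx)^2)
    thick <- c(thick, max(rr) - min(rr))
  }
  expect_lt(min(thick), 2.5)
  expect_gt(max(thick), 3)
})

test_that("volume cases stack drifting slices with shared structure", {
  spec <- syntheticSpec()
  v <- generateVolumeCase(spec, 1, nSlices = 8)
  expect_equal(dim(v$image), c(64, 64, 8))
  expect_equal(dim(v$label), c(64, 64, 8))
  # neighbouring slices overlap strongly (slow drift)
  d <- dsc(v$label[, , 4] == 1, v$label[, , 5] == 1)
  expect_gt(d, 0.8)
  expect_identical(v$label, generateVolumeCase(spec, 1, nSlices = 8)$label)
})

test_that("fixture sets round-trip through NIfTI with manifest regeneration", {
  spec <- syntheticSpec(nTrain = 3, nVal = 2, nTest = 2)
  dir <- tempfile("fixtures")
  writeFixtureSet(spec, dir)
  back <- readFixtureSet(dir)
  ds <- generateDataset(spec)
  expect_equal(length(back$train), 3)
  expect_identical(back$train[[2]]$label, ds$train[[2]]$label)
  expect_equal(back$train[[2]]$image, ds$train[[2]]$image, tolerance = 1e-6)
  # manifest describes the spec well enough to regenerate the set
  mf <- back$manifest
  spec2 <- syntheticSpec(imageSize = mf$imageSize, numClasses = mf$numClasses,
                         nTrain = mf$nTrain, nVal = mf$nVal, nTest = mf$nTest,
                         noiseSd = mf$noiseSd, seed = mf$seed)
  ds2 <- generateDataset(spec2)
  expect_identical(ds2$test[[1]]$label, ds$test[[1]]$label)
  unlink(dir, recursive = TRUE)
})

test_that("dataset splits use disjoint case seeds", {
  spec <- syntheticSpec(nTrain = 3, nVal = 3, nTest = 3)
  ds <- generateDataset(spec)
  expect_false(identical(ds$train[[1]]$label, ds$val[[1]]$label))
  expect_false(identical(ds$val[[1]]$label, ds$test[[1]]$label))
})
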