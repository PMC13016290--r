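# Dice and 95th-percentile Hausdorff metrics against enumeration oracles.

test_that("dsc matches pixel-enumeration cases and is symmetric", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE          # |Mp| = 4
  b <- matrix(FALSE, 4, 4)
  b[cbind(c(1, 1, 2, 3, 3, 3), c(1, 2, 1, 1, 2, 3))] <- TRUE  # |Mg| = 6
  expect_equal(sum(a), 4)
  expect_equal(sum(b), 6)
  expect_equal(sum(a & b), 3)
  expect_equal(dsc(a, b), 2 * 3 / (4 + 6))
  expect_equal(dsc(a, b), dsc(b, a))

  m <- matrix(runif(25) < 0.5, 5, 5)
  expect_equal(dsc(m, m), 1)

  d1 <- matrix(FALSE, 3, 3); d1[1, 1] <- TRUE
  d2 <- matrix(FALSE, 3, 3); d2[3, 3] <- TRUE
  expect_equal(dsc(d1, d2), 0)                           # disjoint nonempty

  e <- matrix(FALSE, 3, 3)
  expect_equal(dsc(e, e), 1)                             # both empty
  expect_equal(dsc(d1, e), 0)                            # one empty
  expect_error(dsc(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shapes")
})

test_that("dsc stays in [0,1] and symmetric on random masks", {
  set.seed(101)
  for (i in 1:50) {
    a <- randomMask(7, 9)
    b <- randomMask(7, 9)
    v <- dsc(a, b)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(v, dsc(b, a))
  }
})

test_that("hd95 handles exact small cases", {
  m <- matrix(FALSE, 10, 10); m[3:6, 4:7] <- TRUE
  expect_equal(hd95(m, m), 0)

  a <- matrix(FALSE, 10, 10); a[2, 2] <- TRUE
  b <- matrix(FALSE, 10, 10); b[7, 2] <- TRUE            # 5 voxels apart
  expect_equal(hd95(a, b), 5)
  expect_equal(hd95(a, b, spacing = c(2, 1)), 10)        # spacing-aware

  e <- matrix(FALSE, 5, 5)
  expect_true(is.na(hd95(e, e)))                         # undefined, not 0
  expect_true(is.na(hd95(a, matrix(FALSE, 10, 10))))
})

test_that("hd95 equals the exhaustive all-pairs oracle on random masks", {
  set.seed(202)
  checked <- 0
  for (i in 1:200) {
    h <- sample(5:15, 1); w <- sample(5:15, 1)
    a <- randomMask(h, w, runif(1, 0.1, 0.6))
    b <- randomMask(h, w, runif(1, 0.1, 0.6))
    got <- hd95(a, b)
    ref <- oracleHd(a, b)
    if (is.na(ref)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, ref, tolerance = 1e-12)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 100)
})

test_that("hd95 never exceeds the classical Hausdorff distance", {
  set.seed(303)
  for (i in 1:40) {
    a <- randomMask(12, 12, 0.4)
    b <- randomMask(12, 12, 0.4)
    v95 <- hd95(a, b)
    v100 <- hd95(a, b, percentile = 1)
    if (!is.na(v95)) expect_lte(v95, v100 + 1e-12)
  }
})

test_that("hd95 agrees with the oracle on 3D volumes", {
  set.seed(404)
  for (i in 1:10) {
    a <- array(runif(6 * 6 * 4) < 0.4, c(6, 6, 4))
    b <- array(runif(6 * 6 * 4) < 0.4, c(6, 6, 4))
    ref <- oracleHd(a, b, spacing = c(1, 1, 2.5))
    got <- hd95(a, b, spacing = c(1, 1, 2.5))
    if (is.na(ref)) expect_true(is.na(got)) else expect_equal(got, ref)
  }
})

test_that("aggregation averages per class then over classes", {
  rec <- evalRecords(case = c(1, 1, 2, 2), class = c(1, 2, 1, 2),
                     dsc = c(0.8, 0.6, 0.9, 0.7),
                     hd95 = c(2, 4, 3, NA))
  agg <- aggregateRecords(rec)
  expect_equal(agg$perClass$dsc, c((0.8 + 0.9) / 2, (0.6 + 0.7) / 2))
  expect_equal(agg$meanDsc, mean(c(0.85, 0.65)))
  expect_equal(agg$perClass$hd95, c(2.5, 4))             # NA excluded
  expect_equal(agg$hd95Excluded, 1)

  one <- evalRecords(case = 1:3, class = rep(1, 3), dsc = rep(1, 3),
                     hd95 = rep(0, 3))
  expect_equal(aggregateRecords(one)$meanDsc, 1)
  expect_error(aggregateRecords(one[0, ]), "no records")
  expect_error(evalRecords(case = c(1, 1), class = c(1, 1),
                           dsc = c(1, 1), hd95 = c(0, 0)),
               "one record per")
})

test_that("evaluateSegmentation produces one record per case and class", {
  set.seed(7)
  gt <- list(matrix(sample(0:2, 64, TRUE), 8, 8),
             matrix(sample(0:2, 64, TRUE), 8, 8))
  rec <- evaluateSegmentation(gt, gt, classes = 1:2)
  expect_equal(nrow(rec), 4)
  expect_true(all(rec$dsc == 1))
  expect_true(all(rec$hd95 == 0 | is.na(rec$hd95)))
})
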