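# Paired Wilcoxon signed-rank test and bootstrap confidence intervals.

test_that("all-positive distinct differences give the extreme exact p", {
  d <- seq(0.5, 6, length.out = 12)
  res <- pairedWilcoxon(d)
  expect_equal(res$statistic, 12 * 13 / 2)
  expect_equal(res$p, 2 / 2^12, tolerance = 1e-12)
  expect_equal(res$meanDiff, mean(d))
})

test_that("exact p matches full sign-assignment enumeration for n <= 10", {
  set.seed(515)
  for (trial in 1:40) {
    n <- sample(4:10, 1)
    d <- sample(-5:5, n, replace = TRUE)  # integer diffs: ties and zeros
    if (all(d == 0)) d[1] <- 1
    got <- suppressWarnings(pairedWilcoxon(d))
    expect_equal(got$p, oracleWilcoxon(d), tolerance = 1e-10,
                 label = paste("diffs:", paste(d, collapse = ",")))
  }
})

test_that("exact p agrees with the reference implementation when tie-free", {
  set.seed(616)
  for (trial in 1:20) {
    n <- sample(6:20, 1)
    d <- round(rnorm(n), 6)
    while (any(d == 0) || anyDuplicated(abs(d))) d <- round(rnorm(n), 6)
    got <- pairedWilcoxon(d)
    ref <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(got$p, ref, tolerance = 1e-10)
  }
})

test_that("symmetric differences sit at the null centre", {
  d <- c(1, -1, 2, -2, 3, -3, 4, -4)
  res <- pairedWilcoxon(d)
  expect_equal(res$meanDiff, 0)
  expect_gte(res$p, 0.9)
})

test_that("zero differences are dropped with a reported count", {
  res <- suppressWarnings(pairedWilcoxon(c(0, 0, 1, 2, 3)))
  expect_equal(res$n, 3)
  expect_equal(res$nZeros, 2)
  expect_warning(pairedWilcoxon(c(0, 0, 0)), "zero")
  expect_equal(suppressWarnings(pairedWilcoxon(c(0, 0)))$p, 1)
})

test_that("an outlier shifts the rank statistic as hand computation says", {
  # |d| ranks: 0.1->1, 0.2->2, 0.3->3, 0.4->4, 0.5->5, 10->6
  d <- c(-0.1, -0.2, -0.3, -0.4, -0.5, 10)
  res <- pairedWilcoxon(d)
  expect_equal(res$statistic, 6)  # only the outlier is positive
  # enumeration oracle agrees
  expect_equal(res$p, oracleWilcoxon(d), tolerance = 1e-10)
})

test_that("large-n path falls back to the normal approximation", {
  set.seed(717)
  d <- rnorm(60, 0.3)
  got <- pairedWilcoxon(d)
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
  expect_equal(got$p, ref, tolerance = 0.02)
})

test_that("bootstrap CI is degenerate on constant input and seed-stable", {
  ci <- bootstrapCI(rep(3.5, 10), seed = 1)
  expect_equal(ci, c(3.5, 3.5))
  set.seed(1); v <- rnorm(20)
  expect_identical(bootstrapCI(v, seed = 42), bootstrapCI(v, seed = 42))
})

test_that("bootstrap interval covers the sample mean on random data", {
  set.seed(818)
  for (i in 1:100) {
    v <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 2))
    ci <- bootstrapCI(v, B = 1000, seed = i)
    expect_lte(ci[1], mean(v) + 1e-9)
    expect_gte(ci[2], mean(v) - 1e-9)
  }
})

test_that("bootstrap leaves the global RNG stream untouched when seeded", {
  v <- rnorm(5)
  set.seed(5)
  before <- runif(1)
  set.seed(5)
  invisible(bootstrapCI(v, seed = 3))
  expect_identical(runif(1), before)
})

test_that("comparing identical record tables yields p = 1 and zero delta", {
  rec <- evalRecords(case = rep(1:6, each = 2), class = rep(1:2, 6),
                     dsc = runif(12, 0.7, 0.95), hd95 = runif(12, 1, 8))
  res <- suppressWarnings(compareRecords(rec, rec))
  expect_equal(res$p, c(1, 1))
  expect_equal(res$meanDiff, c(0, 0))
  expect_equal(res$ciLo, c(0, 0))
})
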