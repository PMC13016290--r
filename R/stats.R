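# Paired nonparametric significance analysis: Wilcoxon signed-rank test with
# an exact tie-aware null distribution for small n, and percentile bootstrap
# confidence intervals.

# Exact null distribution of the signed-rank sum with (possibly tied)
# ranks: dynamic programming over doubled ranks (integers even with .5 ties).
signedRankExactP <- function(ranks, wobs) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1:(total + 1L - r)]
    f <- g
  }
  f <- f / 2^length(r2)
  w2 <- as.integer(round(2 * wobs))
  pLe <- sum(f[seq_len(w2 + 1L)])
  pGe <- sum(f[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(pLe, pGe))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences. Zero differences are dropped
#' (classical policy; the count is reported). For `n <= 25` retained
#' differences the p-value uses the exact null distribution of the
#' signed-rank statistic (tie-aware enumeration by dynamic programming);
#' above that a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param diffs numeric vector of paired differences.
#' @param exactMax largest n for which the exact distribution is used.
#' @return list with `p`, `statistic` (rank sum of positive differences),
#'   `n` (retained), `nZeros` (dropped), `meanDiff` (of all differences).
#' @examples
#' pairedWilcoxon(c(0.5, 1.2, 0.3, 2.0, 0.9, 1.1))
#' @export
pairedWilcoxon <- function(diffs, exactMax = 25L) {
  stopifnot(is.numeric(diffs), length(diffs) >= 1)
  meanDiff <- mean(diffs)
  nz <- sum(diffs == 0)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(p = 1, statistic = 0, n = 0L, nZeros = nz,
                meanDiff = meanDiff))
  }
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  if (n <= exactMax) {
    p <- signedRankExactP(rk, W)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(p = p, statistic = W, n = n, nZeros = nz, meanDiff = meanDiff)
}

#' Percentile bootstrap confidence interval for the mean
#'
#' Resamples with replacement `B` times, computes the mean of each
#' resample, and returns the central `level` percentile interval.
#' Deterministic given `seed` (the global RNG state is restored on exit).
#'
#' @param values numeric vector (n >= 1; constant input yields a degenerate
#'   interval).
#' @param B number of bootstrap iterations.
#' @param level confidence level.
#' @param seed RNG seed; `NULL` uses (and advances) the current RNG state.
#' @return numeric `c(lo, hi)`.
#' @export
bootstrapCI <- function(values, B = 1000L, level = 0.95, seed = NULL) {
  stopifnot(length(values) >= 1, B >= 1, level > 0, level < 1)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  n <- length(values)
  bs <- vapply(seq_len(B),
               function(i) mean(values[sample.int(n, n, replace = TRUE)]), 0)
  a <- (1 - level) / 2
  stats::quantile(bs, c(a, 1 - a), names = FALSE, type = 7)
}

#' Paired comparison of two evaluation-record tables
#'
#' Computes per-case averages (over classes) of DSC and HD95 for two
#' methods, then runs the paired Wilcoxon signed-rank test and a percentile
#' bootstrap interval on the per-case differences (method B minus method A)
#' for each metric.
#'
#' @param recA,recB records data.frames (see [evalRecords()]) with matching
#'   case sets.
#' @param B,level,seed bootstrap parameters.
#' @return data.frame with one row per metric: p-value, mean difference and
#'   bootstrap CI bounds.
#' @export
compareRecords <- function(recA, recB, B = 1000L, level = 0.95, seed = 1L) {
  perCase <- function(r, col) {
    v <- tapply(r[[col]], r$case, mean, na.rm = TRUE)
    v[order(as.numeric(names(v)))]
  }
  out <- list()
  for (metric in c("dsc", "hd95")) {
    a <- perCase(recA, metric)
    b <- perCase(recB, metric)
    if (!identical(names(a), names(b))) stop("case sets differ")
    d <- as.numeric(b - a)
    d <- d[is.finite(d)]
    wt <- suppressWarnings(pairedWilcoxon(d))
    ci <- bootstrapCI(d, B = B, level = level, seed = seed)
    out[[metric]] <- data.frame(metric = metric, p = wt$p,
                                meanDiff = wt$meanDiff,
                                ciLo = ci[1], ciHi = ci[2], n = wt$n)
  }
  do.call(rbind, out)
}
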