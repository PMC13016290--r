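# Segmentation quality metrics: Dice similarity coefficient and
# 95th-percentile symmetric Hausdorff distance, with per-case/per-class
# aggregation.

asMask <- function(x) {
  if (is.logical(x)) x else x != 0
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |Mp intersect Mg| / (|Mp| + |Mg|)`. Symmetric in its arguments.
#' Conventions for degenerate inputs: both masks empty gives 1 (perfect
#' agreement on absence), exactly one empty gives 0.
#'
#' @param pred,gt binary masks (logical or 0/1 arrays) of identical shape,
#'   2D or 3D.
#' @return a value in `[0, 1]`.
#' @examples
#' a <- matrix(c(1,1,0,0), 2); b <- matrix(c(1,0,1,0), 2)
#' dsc(a, b)
#' @export
dsc <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("mask shapes differ")
  p <- asMask(pred); g <- asMask(gt)
  sp <- sum(p); sg <- sum(g)
  if (sp + sg == 0) return(1)
  2 * sum(p & g) / (sp + sg)
}

# Boundary voxels: foreground with at least one face-adjacent background
# neighbour; voxels on the array border count as boundary (outside is
# treated as background). 4-connectivity in 2D, 6 in 3D.
boundaryPoints <- function(mask) {
  m <- asMask(mask)
  d <- dim(m)
  if (is.null(d)) d <- dim(m) <- c(length(m), 1L)
  bg <- !m
  nb <- array(FALSE, d)
  if (length(d) == 2) {
    H <- d[1]; W <- d[2]
    nb[1, ] <- TRUE; nb[H, ] <- TRUE; nb[, 1] <- TRUE; nb[, W] <- TRUE
    if (H > 1) {
      nb[2:H, ] <- nb[2:H, ] | bg[1:(H - 1), ]
      nb[1:(H - 1), ] <- nb[1:(H - 1), ] | bg[2:H, ]
    }
    if (W > 1) {
      nb[, 2:W] <- nb[, 2:W] | bg[, 1:(W - 1)]
      nb[, 1:(W - 1)] <- nb[, 1:(W - 1)] | bg[, 2:W]
    }
  } else if (length(d) == 3) {
    H <- d[1]; W <- d[2]; Z <- d[3]
    nb[1, , ] <- TRUE; nb[H, , ] <- TRUE
    nb[, 1, ] <- TRUE; nb[, W, ] <- TRUE
    nb[, , 1] <- TRUE; nb[, , Z] <- TRUE
    if (H > 1) {
      nb[2:H, , ] <- nb[2:H, , ] | bg[1:(H - 1), , ]
      nb[1:(H - 1), , ] <- nb[1:(H - 1), , ] | bg[2:H, , ]
    }
    if (W > 1) {
      nb[, 2:W, ] <- nb[, 2:W, ] | bg[, 1:(W - 1), ]
      nb[, 1:(W - 1), ] <- nb[, 1:(W - 1), ] | bg[, 2:W, ]
    }
    if (Z > 1) {
      nb[, , 2:Z] <- nb[, , 2:Z] | bg[, , 1:(Z - 1)]
      nb[, , 1:(Z - 1)] <- nb[, , 1:(Z - 1)] | bg[, , 2:Z]
    }
  } else stop("masks must be 2D or 3D")
  which(m & nb, arr.ind = TRUE)
}

#' 95th-percentile symmetric Hausdorff distance
#'
#' Boundary points are extracted from both masks (face-adjacent background
#' neighbour rule), directed nearest-neighbour distances are computed in both
#' directions, the `percentile` quantile (linear interpolation between order
#' statistics) of each direction is taken and the maximum returned.
#' Symmetric under argument swap by construction.
#'
#' @param pred,gt binary masks of identical shape (2D or 3D).
#' @param spacing voxel spacing per axis (e.g. mm); default unit voxels.
#' @param percentile quantile of the directed distance distributions
#'   (1 gives the classical Hausdorff distance).
#' @return distance `>= 0`, or `NA` (undefined) when either mask is empty.
#' @export
hd95 <- function(pred, gt, spacing = NULL, percentile = 0.95) {
  if (!all(dim(pred) == dim(gt))) stop("mask shapes differ")
  bp <- boundaryPoints(pred)
  bg <- boundaryPoints(gt)
  if (nrow(bp) == 0 || nrow(bg) == 0) return(NA_real_)
  if (!is.null(spacing)) {
    if (length(spacing) != ncol(bp)) stop("spacing length must match dims")
    if (any(spacing <= 0)) stop("spacing must be positive")
    bp <- sweep(bp, 2, spacing, "*")
    bg <- sweep(bg, 2, spacing, "*")
  }
  d1 <- cpp_nn_dists(bp, bg)
  d2 <- cpp_nn_dists(bg, bp)
  max(stats::quantile(d1, percentile, names = FALSE, type = 7),
      stats::quantile(d2, percentile, names = FALSE, type = 7))
}

#' Per-case, per-class evaluation records
#'
#' @param case case identifiers.
#' @param class class identifiers (foreground class labels).
#' @param dsc Dice values in `[0, 1]`.
#' @param hd95 HD95 values (`NA` = undefined: a mask was empty).
#' @return a data.frame with one row per (case, class).
#' @export
evalRecords <- function(case, class, dsc, hd95) {
  df <- data.frame(case = case, class = class, dsc = dsc, hd95 = hd95,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("case", "class")]))
    stop("one record per (case, class) required")
  if (any(df$dsc < 0 | df$dsc > 1, na.rm = TRUE)) stop("dsc outside [0, 1]")
  if (any(df$hd95 < 0, na.rm = TRUE)) stop("hd95 must be >= 0")
  df
}

#' Aggregate evaluation records
#'
#' Means are taken over cases within each class, then over classes (grand
#' mean). Undefined HD95 records are excluded from HD95 means; the excluded
#' count is reported.
#'
#' @param records a data.frame from [evalRecords()].
#' @return list with `perClass` (data.frame), `meanDsc`, `meanHd95`,
#'   `hd95Excluded`.
#' @export
aggregateRecords <- function(records) {
  if (nrow(records) == 0) stop("no records to aggregate")
  cls <- sort(unique(records$class))
  perClass <- do.call(rbind, lapply(cls, function(k) {
    r <- records[records$class == k, ]
    data.frame(class = k,
               dsc = mean(r$dsc),
               hd95 = if (all(is.na(r$hd95))) NA_real_
                      else mean(r$hd95, na.rm = TRUE),
               n = nrow(r),
               hd95Excluded = sum(is.na(r$hd95)))
  }))
  list(perClass = perClass,
       meanDsc = mean(perClass$dsc),
       meanHd95 = mean(perClass$hd95, na.rm = TRUE),
       hd95Excluded = sum(perClass$hd95Excluded))
}

#' Evaluate predicted label maps against ground truth
#'
#' Computes one (case, class) record per foreground class per case. Cases
#' may be 2D label maps or reassembled 3D volumes (slices stacked per case),
#' which is the conventional per-case evaluation mode for abdominal CT
#' benchmarks.
#'
#' @param pred,gt lists of integer label arrays (one element per case).
#' @param classes foreground class values to score.
#' @param spacing voxel spacing forwarded to [hd95()].
#' @return records data.frame as from [evalRecords()].
#' @export
evaluateSegmentation <- function(pred, gt, classes, spacing = NULL) {
  stopifnot(length(pred) == length(gt))
  rows <- list()
  for (i in seq_along(pred)) {
    for (k in classes) {
      pm <- pred[[i]] == k
      gm <- gt[[i]] == k
      rows[[length(rows) + 1L]] <- data.frame(
        case = i, class = k, dsc = dsc(pm, gm),
        hd95 = hd95(pm, gm, spacing))
    }
  }
  do.call(rbind, rows)
}
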