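# Synthetic multi-class organ-phantom generator. Phantoms contain up to
# three disjoint foreground structures on background: a large elliptical
# blob, a thin annulus (1-4 px wall, the thin-structure failure mode of
# cardiac myocardium), and a small ellipse. Class-conditional intensities
# are evenly spaced with additive Gaussian noise, so the task is learnable
# by construction but still exercises boundaries at all scales.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

ellipseMask <- function(S, cy, cx, a, b, theta) {
  gy <- matrix(seq_len(S), S, S)
  gx <- matrix(seq_len(S), S, S, byrow = TRUE)
  dy <- gy - cy; dx <- gx - cx
  u <- cos(theta) * dy + sin(theta) * dx
  v <- -sin(theta) * dy + cos(theta) * dx
  (u / a)^2 + (v / b)^2 <= 1
}

annulusMask <- function(S, cy, cx, router, rinner) {
  gy <- matrix(seq_len(S), S, S)
  gx <- matrix(seq_len(S), S, S, byrow = TRUE)
  d2 <- (gy - cy)^2 + (gx - cx)^2
  d2 <= router^2 & d2 > rinner^2
}

# class mean intensities: evenly spaced over the contrast range with a small
# per-case jitter (keeps K distinct values; spacing still >= 2 * noiseSd)
classMeans <- function(spec) {
  k <- spec@numClasses
  base <- seq(spec@contrast[1], spec@contrast[2], length.out = k)
  jit <- stats::runif(k, -0.02, 0.02)
  pmin(pmax(base + jit, 0), 1)
}

#' Generate one synthetic segmentation case
#'
#' Draws a label map of disjoint parametric shapes with random pose and
#' scale, then renders the image as per-class mean intensity plus Gaussian
#' noise, clipped to `[0, 1]`. The ring (class 3) and small ellipse
#' (class 4) are each independently omitted with probability
#' `spec@dropoutProb`, emulating missing small organs. Shape poses that
#' would overlap an earlier structure or produce a degenerate ring are
#' rejected and redrawn (the retry count is returned).
#'
#' @param spec a [SyntheticSpec-class].
#' @param index case index; the case RNG seed is `spec@seed + index` so any
#'   case regenerates identically in isolation.
#' @return list with `image` (S x S in `[0, 1]`), `label` (S x S integers
#'   `0..K-1`), `means` (class intensities) and `retries`.
#' @export
generateCase <- function(spec, index = 1L) {
  withSeed(spec@seed + as.integer(index), {
    S <- spec@imageSize
    K <- spec@numClasses
    label <- matrix(0L, S, S)
    means <- classMeans(spec)
    retries <- 0L

    place <- function(makeMask) {
      for (try in 1:40) {
        mk <- makeMask()
        if (!is.null(mk) && sum(mk) > 0 && !any(mk & label > 0)) return(mk)
        retries <<- retries + 1L
      }
      NULL
    }

    if (K >= 2) {  # large blob
      mk <- place(function() {
        ellipseMask(S, stats::runif(1, 0.3, 0.7) * S, stats::runif(1, 0.3, 0.7) * S,
                    stats::runif(1, 0.16, 0.26) * S, stats::runif(1, 0.12, 0.22) * S,
                    stats::runif(1, 0, pi))
      })
      if (!is.null(mk)) label[mk] <- 1L
    }
    if (K >= 3 && stats::runif(1) >= spec@dropoutProb) {  # thin ring
      mk <- place(function() {
        R <- stats::runif(1, 0.10, 0.18) * S
        t <- stats::runif(1, 1, 4)
        if (R - t < 1) return(NULL)  # degenerate ring: reject and redraw
        annulusMask(S, stats::runif(1, 0.2, 0.8) * S, stats::runif(1, 0.2, 0.8) * S,
                    R, R - t)
      })
      if (!is.null(mk)) label[mk] <- 2L
    }
    if (K >= 4 && stats::runif(1) >= spec@dropoutProb) {  # small ellipse
      mk <- place(function() {
        ellipseMask(S, stats::runif(1, 0.15, 0.85) * S, stats::runif(1, 0.15, 0.85) * S,
                    stats::runif(1, 0.04, 0.08) * S, stats::runif(1, 0.04, 0.08) * S,
                    stats::runif(1, 0, pi))
      })
      if (!is.null(mk)) label[mk] <- 3L
    }
    img <- matrix(means[label + 1L], S, S)
    if (spec@noiseSd > 0)
      img <- img + matrix(stats::rnorm(S * S, 0, spec@noiseSd), S, S)
    img <- pmin(pmax(img, 0), 1)
    list(image = img, label = label, means = means, retries = retries)
  })
}

#' Generate a correlated slice stack (pseudo-3D case)
#'
#' Stacks `nSlices` phantoms whose shape poses drift slowly along z (a small
#' random walk on the case's base pose), so per-case evaluation on
#' reassembled volumes is exercised.
#'
#' @param spec a [SyntheticSpec-class].
#' @param index case index (seeds the case).
#' @param nSlices number of slices; default drawn uniformly from 8..16.
#' @return list with `image` and `label` arrays of dim `(S, S, nSlices)`.
#' @export
generateVolumeCase <- function(spec, index = 1L, nSlices = NULL) {
  withSeed(spec@seed + 500000L + as.integer(index), {
    if (is.null(nSlices)) nSlices <- sample(8:16, 1)
    S <- spec@imageSize
    means <- classMeans(spec)
    cy <- stats::runif(1, 0.35, 0.65) * S
    cx <- stats::runif(1, 0.35, 0.65) * S
    a <- stats::runif(1, 0.16, 0.24) * S
    b <- stats::runif(1, 0.12, 0.2) * S
    rcy <- stats::runif(1, 0.2, 0.8) * S
    rcx <- stats::runif(1, 0.2, 0.8) * S
    R <- stats::runif(1, 0.10, 0.16) * S
    t <- stats::runif(1, 1.5, 4)
    img <- array(0, c(S, S, nSlices))
    lab <- array(0L, c(S, S, nSlices))
    for (z in seq_len(nSlices)) {
      lz <- matrix(0L, S, S)
      blob <- ellipseMask(S, cy, cx, a, b, 0)
      lz[blob] <- 1L
      ring <- annulusMask(S, rcy, rcx, R, max(R - t, 1))
      lz[ring & lz == 0L] <- 2L
      iz <- matrix(means[lz + 1L], S, S)
      if (spec@noiseSd > 0)
        iz <- iz + matrix(stats::rnorm(S * S, 0, spec@noiseSd), S, S)
      img[, , z] <- pmin(pmax(iz, 0), 1)
      lab[, , z] <- lz
      # slow drift of the poses along z
      cy <- cy + stats::rnorm(1, 0, 0.01 * S)
      cx <- cx + stats::rnorm(1, 0, 0.01 * S)
      a <- max(3, a + stats::rnorm(1, 0, 0.01 * S))
      b <- max(3, b + stats::rnorm(1, 0, 0.01 * S))
      rcy <- rcy + stats::rnorm(1, 0, 0.01 * S)
      rcx <- rcx + stats::rnorm(1, 0, 0.01 * S)
      R <- max(4, R + stats::rnorm(1, 0, 0.005 * S))
    }
    list(image = img, label = lab)
  })
}

#' Generate the train/val/test phantom dataset
#'
#' Case seeds are disjoint across splits (`spec@seed + index`, with offsets
#' 0 / 100000 / 200000), so splits never share a case.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list of three lists of cases: `train`, `val`, `test`.
#' @export
generateDataset <- function(spec) {
  mk <- function(n, offset) {
    lapply(seq_len(n), function(i) generateCase(spec, offset + i))
  }
  list(train = mk(spec@nTrain, 0L),
       val = mk(spec@nVal, 100000L),
       test = mk(spec@nTest, 200000L))
}

#' Write a phantom fixture set to disk
#'
#' Writes each split as a pair of NIfTI volumes (slices stacked along z:
#' `<split>_images.nii.gz` float, `<split>_labels.nii.gz` integer) plus a
#' JSON manifest recording the generator specification and split seeds, so
#' the set can be regenerated bit-for-bit or read back through the NIfTI
#' input path.
#'
#' @param spec a [SyntheticSpec-class].
#' @param path output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
writeFixtureSet <- function(spec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ds <- generateDataset(spec)
  for (split in names(ds)) {
    cases <- ds[[split]]
    if (length(cases) == 0) next
    S <- spec@imageSize
    img <- array(0, c(S, S, length(cases)))
    lab <- array(0L, c(S, S, length(cases)))
    for (i in seq_along(cases)) {
      img[, , i] <- cases[[i]]$image
      lab[, , i] <- cases[[i]]$label
    }
    RNifti::writeNifti(RNifti::asNifti(img),
                       file.path(path, paste0(split, "_images.nii.gz")))
    RNifti::writeNifti(RNifti::asNifti(lab),
                       file.path(path, paste0(split, "_labels.nii.gz")))
  }
  manifest <- list(
    generator = "sceafunet phantom generator",
    imageSize = spec@imageSize, numClasses = spec@numClasses,
    nTrain = spec@nTrain, nVal = spec@nVal, nTest = spec@nTest,
    noiseSd = spec@noiseSd, contrast = spec@contrast,
    dropoutProb = spec@dropoutProb, seed = spec@seed,
    seedOffsets = list(train = 0L, val = 100000L, test = 200000L))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a phantom fixture set written by [writeFixtureSet()]
#'
#' @param path fixture directory.
#' @return list with per-split case lists and the manifest.
#' @export
readFixtureSet <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  out <- list()
  for (split in c("train", "val", "test")) {
    f <- file.path(path, paste0(split, "_images.nii.gz"))
    if (!file.exists(f)) next
    img <- as.array(RNifti::readNifti(f))
    lab <- as.array(RNifti::readNifti(
      file.path(path, paste0(split, "_labels.nii.gz"))))
    out[[split]] <- lapply(seq_len(dim(img)[3]), function(i) {
      list(image = img[, , i], label = matrix(as.integer(lab[, , i]),
                                              nrow(lab), ncol(lab)))
    })
  }
  out$manifest <- manifest
  out
}
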