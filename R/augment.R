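# Online geometric augmentation, slice preprocessing and deterministic
# test-time augmentation. The image and label always receive identical
# geometry; labels are always interpolated nearest-neighbour.

rot90mat <- function(m, k) {
  k <- ((k %% 4) + 4) %% 4
  for (i in seq_len(k)) {
    m <- t(m)
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
  m
}

flipmat <- function(m, axis) {
  if (axis == 1) m[rev(seq_len(nrow(m))), , drop = FALSE]
  else m[, rev(seq_len(ncol(m))), drop = FALSE]
}

#' Augment one segmentation sample
#'
#' Draws from the global RNG (seed with [set.seed()]): with probability
#' `pGeo`, a rotation by a uniform multiple of 90 degrees combined with a
#' random flip (one axis chosen uniformly, applied with probability 0.5) —
#' a bijective pixel permutation, so per-class pixel counts are preserved
#' exactly; otherwise, with conditional probability `pSmallRot`, a
#' continuous rotation uniform in `[-maxAngle, maxAngle]` degrees (bilinear
#' for the image, nearest for the label, background fill); otherwise the
#' sample passes through unchanged.
#'
#' @param image,label matrices of identical shape.
#' @param policy an [AugmentPolicy-class].
#' @return list with `image`, `label` and `branch` (one of `"geo"`,
#'   `"smallrot"`, `"identity"`).
#' @export
augmentSample <- function(image, label, policy = augmentPolicy()) {
  stopifnot(all(dim(image) == dim(label)))
  if (stats::runif(1) < policy@pGeo) {
    k <- sample(0:3, 1)
    axis <- sample(1:2, 1)
    doFlip <- stats::runif(1) < 0.5
    img <- rot90mat(image, k)
    lab <- rot90mat(label, k)
    if (doFlip) {
      img <- flipmat(img, axis)
      lab <- flipmat(lab, axis)
    }
    list(image = img, label = lab, branch = "geo")
  } else if (stats::runif(1) < policy@pSmallRot) {
    ang <- stats::runif(1, -policy@maxAngle, policy@maxAngle)
    img <- cpp_rotate2d(image, ang, 1L, 0)
    lab <- matrix(as.integer(cpp_rotate2d(label + 0, ang, 0L, 0)),
                  nrow(label), ncol(label))
    list(image = img, label = lab, branch = "smallrot")
  } else {
    list(image = image, label = label, branch = "identity")
  }
}

#' Preprocess an image/label volume into model-ready slices
#'
#' Resizes each axial slice to `targetSize` x `targetSize`. Image
#' interpolation is bicubic (CT-style mode) or nearest (MR-style mode);
#' labels always use nearest-neighbour, so no new class values can appear.
#'
#' @param imageVol,labelVol arrays of dim `(H, W, Z)` (a matrix is treated
#'   as a single slice).
#' @param targetSize output side length.
#' @param imageMethod `"bicubic"` or `"nearest"`.
#' @return list of samples, each `list(image, label)`.
#' @export
preprocessVolume <- function(imageVol, labelVol, targetSize = 224L,
                             imageMethod = c("bicubic", "nearest")) {
  imageMethod <- match.arg(imageMethod)
  if (length(dim(imageVol)) == 2) imageVol <- array(imageVol, c(dim(imageVol), 1))
  if (length(dim(labelVol)) == 2) labelVol <- array(labelVol, c(dim(labelVol), 1))
  if (!all(dim(imageVol) == dim(labelVol)))
    stop("image and label volume shapes differ")
  mcode <- if (imageMethod == "bicubic") 2L else 0L
  lapply(seq_len(dim(imageVol)[3]), function(z) {
    img <- cpp_resample2d(imageVol[, , z], targetSize, targetSize, mcode)
    lab <- cpp_resample2d(labelVol[, , z] + 0, targetSize, targetSize, 0L)
    list(image = img,
         label = matrix(as.integer(lab), targetSize, targetSize))
  })
}

softmaxProbs <- function(logits) {
  d <- dim(logits)
  zm <- matrix(logits, prod(d[1:2]), d[3])
  array(softmaxMat(zm), d)
}

ttaTransforms <- function(mode) {
  switch(mode,
    none = list(list(k = 0L, flip = FALSE)),
    flip = list(list(k = 0L, flip = FALSE), list(k = 0L, flip = TRUE)),
    flip_rot90 = {
      tr <- list()
      for (k in 0:3) for (f in c(FALSE, TRUE))
        tr[[length(tr) + 1L]] <- list(k = k, flip = f)
      tr
    },
    stop("unknown TTA mode: ", mode))
}

#' Predict class probabilities with deterministic test-time augmentation
#'
#' Applies a fixed invertible transform set (mode `"flip"`: identity +
#' horizontal flip, 2 forward passes; mode `"flip_rot90"`: horizontal flip
#' crossed with rotations of 0/90/180/270 degrees, 8 passes), inverts each
#' prediction, and averages in softmax-probability space; the result is
#' renormalized so per-pixel class probabilities sum to one.
#'
#' @param model a [SceafModel-class].
#' @param image matrix `(H, W)`.
#' @param mode `"none"`, `"flip"` or `"flip_rot90"`.
#' @return probability array `(H, W, K)`.
#' @export
ttaPredict <- function(model, image, mode = c("flip", "flip_rot90", "none")) {
  mode <- match.arg(mode)
  tr <- ttaTransforms(mode)
  acc <- NULL
  for (t in tr) {
    img <- image
    if (t$flip) img <- flipmat(img, 2)
    img <- rot90mat(img, t$k)
    logits <- modelLogits(model, img, training = FALSE)
    pr <- softmaxProbs(logits)
    # invert: rotate back, then unflip, per class channel
    K <- dim(pr)[3]
    inv <- array(0, c(dim(image), K))
    for (c in seq_len(K)) {
      ch <- rot90mat(pr[, , c], -t$k)
      if (t$flip) ch <- flipmat(ch, 2)
      inv[, , c] <- ch
    }
    acc <- if (is.null(acc)) inv else acc + inv
  }
  acc <- acc / length(tr)
  s <- apply(acc, c(1, 2), sum)
  acc / array(rep(s, dim(acc)[3]), dim(acc))
}

#' Segment a single image
#'
#' @param model a [SceafModel-class].
#' @param image matrix `(H, W)` with H, W divisible by 16.
#' @param tta test-time augmentation mode (see [ttaPredict()]).
#' @return list with `probs` `(H, W, K)` and `label` (integer matrix,
#'   values `0..K-1`).
#' @export
predictSegmentation <- function(model, image,
                                tta = c("none", "flip", "flip_rot90")) {
  tta <- match.arg(tta)
  probs <- if (tta == "none") {
    softmaxProbs(modelLogits(model, image, training = FALSE))
  } else {
    ttaPredict(model, image, tta)
  }
  lab <- apply(probs, c(1, 2), which.max) - 1L
  list(probs = probs, label = matrix(as.integer(lab), nrow(image), ncol(image)))
}
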