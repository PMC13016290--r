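# Hybrid segmentation loss: weighted cross-entropy + soft Dice on softmax
# probabilities (background class included), with analytic gradient wrt the
# logits.

softmaxMat <- function(zm) {
  mx <- zm[, 1]
  for (k in seq_len(ncol(zm))[-1]) mx <- pmax(mx, zm[, k])
  e <- exp(zm - mx)
  e / rowSums(e)
}

#' Hybrid cross-entropy + soft-Dice loss
#'
#' `loss = alpha * CE + beta * (1 - mean_c Dice_c)` where the soft Dice of
#' class c is `(2 * sum(p_c g_c) + eps) / (sum(p_c) + sum(g_c) + eps)`
#' computed on softmax probabilities over all pixels of the batch,
#' background included.
#'
#' @param logits array `(H, W, K)` or batched `(H, W, N, K)`.
#' @param labels integer array `(H, W)` / `(H, W, N)` with values `0..K-1`.
#' @param alpha,beta loss weights (cross-entropy, Dice).
#' @param eps soft-Dice smoothing constant.
#' @param grad also return the gradient wrt the logits.
#' @return list with `loss`, `ce`, `dice` (the Dice loss term) and, when
#'   `grad = TRUE`, `grad` shaped like `logits`.
#' @export
hybridLoss <- function(logits, labels, alpha = 0.5, beta = 0.5, eps = 1e-5,
                       grad = FALSE) {
  dl <- dim(logits)
  if (length(dl) == 3) dim(logits) <- dl <- c(dl[1], dl[2], 1L, dl[3])
  K <- dl[4]
  P <- prod(dl[1:3])
  lab <- as.integer(labels)
  if (length(lab) != P) stop("labels do not match logits batch shape")
  if (any(lab < 0L | lab >= K)) stop("label values must lie in 0..K-1")
  zm <- matrix(logits, P, K)
  p <- softmaxMat(zm)
  idx <- cbind(seq_len(P), lab + 1L)
  ce <- -mean(log(pmax(p[idx], 1e-12)))
  G <- matrix(0, P, K)
  G[idx] <- 1
  num <- 2 * colSums(p * G) + eps
  den <- colSums(p) + colSums(G) + eps
  diceLoss <- 1 - mean(num / den)
  loss <- alpha * ce + beta * diceLoss
  out <- list(loss = loss, ce = ce, dice = diceLoss)
  if (grad) {
    dz_ce <- (p - G) / P
    # d(diceLoss)/dp
    dLdp <- -(sweep(G, 2, 2 * den, "*") - rep(num, each = P)) /
      rep(den^2, each = P) / K
    dz_dice <- p * (dLdp - rowSums(dLdp * p))
    out$grad <- array(alpha * dz_ce + beta * dz_dice, dl)
  }
  out
}
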