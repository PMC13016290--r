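# Minimal reference-semantics conv-net engine.
#
# Feature maps are numeric arrays with dim (H, W, N, C); single samples can be
# promoted with nnBatch(). Every layer is an environment holding params, grads
# and a forward cache; backward passes are hand-derived. Layers are used at
# most once per forward pass, so each caches a single input.

.nn_env <- new.env(parent = emptyenv())
.nn_env$lazy <- FALSE

nnLazy <- function() .nn_env$lazy

# Build modules without allocating weights (budget accounting for very wide
# configurations); describe() only needs layer metadata.
withLazyModules <- function(expr) {
  old <- .nn_env$lazy
  .nn_env$lazy <- TRUE
  on.exit(.nn_env$lazy <- old)
  expr
}

nnModule <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$params <- NULL
  m$grads <- NULL
  m$buffers <- NULL
  m$children <- list()
  m$cache <- NULL
  class(m) <- c(paste0("nn_", type), "nn_module")
  m
}

nnForward <- function(m, x, training = FALSE) UseMethod("nnForward")
nnBackward <- function(m, dy) UseMethod("nnBackward")
# shp = c(H, W, C); returns list(rows = data.frame(params, macs), out = shp)
nnDescribe <- function(m, shp) UseMethod("nnDescribe")

descRow <- function(type, params, macs) {
  data.frame(layer = type, params = params, macs = macs,
             stringsAsFactors = FALSE)
}

## ---- dense convolution (via im2col) ----------------------------------------

nnConv <- function(cin, cout, k = 1L, stride = 1L, pad = (k - 1L) %/% 2L,
                   bias = TRUE) {
  m <- nnModule("conv")
  m$cin <- cin; m$cout <- cout; m$k <- k; m$stride <- stride; m$pad <- pad
  m$bias <- bias
  if (!nnLazy()) {
    sd <- sqrt(2 / (k * k * cin))
    m$params <- list(W = matrix(stats::rnorm(k * k * cin * cout, 0, sd),
                                k * k * cin, cout))
    m$decay <- c(W = TRUE)
    if (bias) {
      m$params$b <- numeric(cout)
      m$decay <- c(m$decay, b = FALSE)
    }
  }
  m
}

nnForward.nn_conv <- function(m, x, training = FALSE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  stopifnot(C == m$cin)
  if (m$k == 1L && m$stride == 1L) {
    M <- matrix(x, H * W * N, C)
    Ho <- H; Wo <- W
  } else {
    M <- cpp_im2col(x, H, W, N, C, m$k, m$stride, m$pad)
    Ho <- (H + 2 * m$pad - m$k) %/% m$stride + 1L
    Wo <- (W + 2 * m$pad - m$k) %/% m$stride + 1L
  }
  y <- M %*% m$params$W
  if (m$bias) y <- y + rep(m$params$b, each = nrow(M))
  m$cache <- list(M = M, din = d, Ho = Ho, Wo = Wo)
  array(y, c(Ho, Wo, N, m$cout))
}

nnBackward.nn_conv <- function(m, dy) {
  cc <- m$cache
  R <- nrow(cc$M)
  dym <- matrix(dy, R, m$cout)
  m$grads$W <- m$grads$W + crossprod(cc$M, dym)
  if (m$bias) m$grads$b <- m$grads$b + colSums(dym)
  dM <- tcrossprod(dym, m$params$W)
  d <- cc$din
  if (m$k == 1L && m$stride == 1L) {
    array(dM, d)
  } else {
    array(cpp_col2im(dM, d[1], d[2], d[3], d[4], m$k, m$stride, m$pad), d)
  }
}

nnDescribe.nn_conv <- function(m, shp) {
  Ho <- (shp[1] + 2 * m$pad - m$k) %/% m$stride + 1L
  Wo <- (shp[2] + 2 * m$pad - m$k) %/% m$stride + 1L
  p <- m$k^2 * m$cin * m$cout + if (m$bias) m$cout else 0
  list(rows = descRow("conv", p, as.numeric(m$k)^2 * m$cin * m$cout * Ho * Wo),
       out = c(Ho, Wo, m$cout))
}

## ---- depthwise convolution -------------------------------------------------

nnDWConv <- function(C, k, bias = TRUE) {
  m <- nnModule("dwconv")
  m$C <- C; m$k <- k; m$bias <- bias
  if (!nnLazy()) {
    sd <- sqrt(2 / (k * k))
    m$params <- list(W = array(stats::rnorm(k * k * C, 0, sd), c(k, k, C)),
                     b = numeric(C))
    m$decay <- c(W = TRUE, b = FALSE)
  }
  m
}

nnForward.nn_dwconv <- function(m, x, training = FALSE) {
  d <- dim(x)
  stopifnot(d[4] == m$C)
  y <- cpp_dwconv_fwd(x, m$params$W, m$params$b, d[1], d[2], d[3], d[4], m$k)
  m$cache <- list(x = x, din = d)
  array(y, d)
}

nnBackward.nn_dwconv <- function(m, dy) {
  d <- m$cache$din
  gw <- cpp_dwconv_bwd_w(m$cache$x, dy, d[1], d[2], d[3], d[4], m$k)
  m$grads$W <- m$grads$W + array(gw$dw, dim(m$params$W))
  m$grads$b <- m$grads$b + gw$db
  array(cpp_dwconv_bwd_x(dy, m$params$W, d[1], d[2], d[3], d[4], m$k), d)
}

nnDescribe.nn_dwconv <- function(m, shp) {
  p <- m$k^2 * m$C + if (m$bias) m$C else 0
  list(rows = descRow("dwconv", p, as.numeric(m$k)^2 * m$C * shp[1] * shp[2]),
       out = c(shp[1], shp[2], m$C))
}

## ---- batch normalization ---------------------------------------------------

nnBN <- function(C, momentum = 0.1, eps = 1e-5) {
  m <- nnModule("bn")
  m$C <- C; m$momentum <- momentum; m$eps <- eps
  if (!nnLazy()) {
    m$params <- list(gamma = rep(1, C), beta = numeric(C))
    m$decay <- c(gamma = FALSE, beta = FALSE)
    m$buffers <- list(rm = numeric(C), rv = rep(1, C))
  }
  m
}

nnForward.nn_bn <- function(m, x, training = FALSE) {
  d <- dim(x)
  L <- d[1] * d[2] * d[3]
  xm <- matrix(x, L, d[4])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    v[v < 0] <- 0
    istd <- 1 / sqrt(v + m$eps)
    xh <- (xm - rep(mu, each = L)) * rep(istd, each = L)
    ub <- if (L > 1) v * L / (L - 1) else v
    m$buffers$rm <- (1 - m$momentum) * m$buffers$rm + m$momentum * mu
    m$buffers$rv <- (1 - m$momentum) * m$buffers$rv + m$momentum * ub
    m$cache <- list(xh = xh, istd = istd, din = d, train = TRUE)
  } else {
    istd <- 1 / sqrt(m$buffers$rv + m$eps)
    xh <- (xm - rep(m$buffers$rm, each = L)) * rep(istd, each = L)
    m$cache <- list(xh = xh, istd = istd, din = d, train = FALSE)
  }
  y <- xh * rep(m$params$gamma, each = L) + rep(m$params$beta, each = L)
  array(y, d)
}

nnBackward.nn_bn <- function(m, dy) {
  cc <- m$cache
  d <- cc$din
  L <- d[1] * d[2] * d[3]
  dym <- matrix(dy, L, d[4])
  m$grads$gamma <- m$grads$gamma + colSums(dym * cc$xh)
  m$grads$beta <- m$grads$beta + colSums(dym)
  dxh <- dym * rep(m$params$gamma, each = L)
  if (cc$train) {
    mdxh <- colMeans(dxh)
    mdxhxh <- colMeans(dxh * cc$xh)
    dx <- (dxh - rep(mdxh, each = L) - cc$xh * rep(mdxhxh, each = L)) *
      rep(cc$istd, each = L)
  } else {
    dx <- dxh * rep(cc$istd, each = L)
  }
  array(dx, d)
}

nnDescribe.nn_bn <- function(m, shp) {
  list(rows = descRow("bn", 2 * m$C, 0), out = c(shp[1], shp[2], m$C))
}

## ---- group normalization ---------------------------------------------------

nnGN <- function(C, groups = 8L, eps = 1e-5) {
  if (C %% groups != 0) {
    # fall back to the largest divisor of C not exceeding the request
    groups <- max(which(C %% seq_len(min(groups, C)) == 0))
  }
  m <- nnModule("gn")
  m$C <- C; m$groups <- as.integer(groups); m$eps <- eps
  if (!nnLazy()) {
    m$params <- list(gamma = rep(1, C), beta = numeric(C))
    m$decay <- c(gamma = FALSE, beta = FALSE)
  }
  m
}

# to/from column layout (H*W*cpg) x (N*groups)
.gn_tocols <- function(x, d, cpg, g) {
  x5 <- array(x, c(d[1], d[2], d[3], cpg, g))
  xp <- aperm(x5, c(1, 2, 4, 3, 5))
  matrix(xp, d[1] * d[2] * cpg, d[3] * g)
}

.gn_fromcols <- function(xm, d, cpg, g) {
  x5 <- array(xm, c(d[1], d[2], cpg, d[3], g))
  array(aperm(x5, c(1, 2, 4, 3, 5)), d)
}

nnForward.nn_gn <- function(m, x, training = FALSE) {
  d <- dim(x)
  g <- m$groups
  cpg <- d[4] %/% g
  L <- d[1] * d[2] * cpg
  xm <- .gn_tocols(x, d, cpg, g)
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  v[v < 0] <- 0
  istd <- 1 / sqrt(v + m$eps)
  xh <- (xm - rep(mu, each = L)) * rep(istd, each = L)
  xhat <- .gn_fromcols(xh, d, cpg, g)
  Lc <- d[1] * d[2] * d[3]
  y <- xhat * rep(m$params$gamma, each = Lc) + rep(m$params$beta, each = Lc)
  m$cache <- list(xh = xh, xhat = xhat, istd = istd, din = d)
  y
}

nnBackward.nn_gn <- function(m, dy) {
  cc <- m$cache
  d <- cc$din
  g <- m$groups
  cpg <- d[4] %/% g
  L <- d[1] * d[2] * cpg
  Lc <- d[1] * d[2] * d[3]
  dym <- matrix(dy, Lc, d[4])
  m$grads$gamma <- m$grads$gamma + colSums(dym * matrix(cc$xhat, Lc, d[4]))
  m$grads$beta <- m$grads$beta + colSums(dym)
  dxhat <- array(dy, d) * rep(m$params$gamma, each = Lc)
  dxh <- .gn_tocols(dxhat, d, cpg, g)
  mdxh <- colMeans(dxh)
  mdxhxh <- colMeans(dxh * cc$xh)
  dxm <- (dxh - rep(mdxh, each = L) - cc$xh * rep(mdxhxh, each = L)) *
    rep(cc$istd, each = L)
  .gn_fromcols(dxm, d, cpg, g)
}

nnDescribe.nn_gn <- function(m, shp) {
  list(rows = descRow("gn", 2 * m$C, 0), out = c(shp[1], shp[2], m$C))
}

## ---- activations -----------------------------------------------------------

nnGelu <- function() nnModule("gelu")
nnForward.nn_gelu <- function(m, x, training = FALSE) {
  m$cache <- x
  x * stats::pnorm(x)
}
nnBackward.nn_gelu <- function(m, dy) {
  x <- m$cache
  dy * (stats::pnorm(x) + x * stats::dnorm(x))
}
nnDescribe.nn_gelu <- function(m, shp) list(rows = NULL, out = shp)

nnRelu <- function() nnModule("relu")
nnForward.nn_relu <- function(m, x, training = FALSE) {
  m$cache <- x > 0
  x * m$cache
}
nnBackward.nn_relu <- function(m, dy) dy * m$cache
nnDescribe.nn_relu <- function(m, shp) list(rows = NULL, out = shp)

nnSigmoid <- function() nnModule("sigmoid")
nnForward.nn_sigmoid <- function(m, x, training = FALSE) {
  y <- 1 / (1 + exp(-x))
  m$cache <- y
  y
}
nnBackward.nn_sigmoid <- function(m, dy) dy * m$cache * (1 - m$cache)
nnDescribe.nn_sigmoid <- function(m, shp) list(rows = NULL, out = shp)

nnTanh <- function() nnModule("tanh")
nnForward.nn_tanh <- function(m, x, training = FALSE) {
  y <- tanh(x)
  m$cache <- y
  y
}
nnBackward.nn_tanh <- function(m, dy) dy * (1 - m$cache^2)
nnDescribe.nn_tanh <- function(m, shp) list(rows = NULL, out = shp)

## ---- resolution / channel rearrangement ------------------------------------

nnUpsample2x <- function() nnModule("up2x")
nnForward.nn_up2x <- function(m, x, training = FALSE) {
  d <- dim(x)
  m$cache <- d
  array(cpp_upsample2x_fwd(x, d[1], d[2], d[3], d[4]),
        c(2 * d[1], 2 * d[2], d[3], d[4]))
}
nnBackward.nn_up2x <- function(m, dy) {
  d <- m$cache
  array(cpp_upsample2x_bwd(dy, d[1], d[2], d[3], d[4]), d)
}
nnDescribe.nn_up2x <- function(m, shp) {
  list(rows = NULL, out = c(2 * shp[1], 2 * shp[2], shp[3]))
}

# Channel shuffle: view channels as (groups, C/groups), transpose, flatten.
channelShufflePerm <- function(C, groups) {
  stopifnot(C %% groups == 0)
  o0 <- seq_len(C) - 1L
  mm <- o0 %/% groups
  gi <- o0 %% groups
  as.integer(gi * (C %/% groups) + mm + 1L)
}

nnShuffle <- function(C, groups) {
  m <- nnModule("shuffle")
  m$C <- C
  m$perm <- channelShufflePerm(C, groups)
  m$invperm <- order(m$perm)
  m
}
nnForward.nn_shuffle <- function(m, x, training = FALSE) x[, , , m$perm, drop = FALSE]
nnBackward.nn_shuffle <- function(m, dy) dy[, , , m$invperm, drop = FALSE]
nnDescribe.nn_shuffle <- function(m, shp) list(rows = NULL, out = shp)

## ---- layer scale / drop path -----------------------------------------------

nnLayerScale <- function(C, init = 1e-6) {
  m <- nnModule("lscale")
  m$C <- C
  if (!nnLazy()) {
    m$params <- list(g = rep(init, C))
    m$decay <- c(g = FALSE)
  }
  m
}
nnForward.nn_lscale <- function(m, x, training = FALSE) {
  d <- dim(x)
  L <- d[1] * d[2] * d[3]
  m$cache <- list(x = x, L = L)
  x * rep(m$params$g, each = L)
}
nnBackward.nn_lscale <- function(m, dy) {
  cc <- m$cache
  d <- dim(cc$x)
  m$grads$g <- m$grads$g +
    colSums(matrix(dy * cc$x, cc$L, d[4]))
  dy * rep(m$params$g, each = cc$L)
}
nnDescribe.nn_lscale <- function(m, shp) {
  list(rows = descRow("lscale", m$C, 0), out = shp)
}

nnDropPath <- function(rate = 0) {
  m <- nnModule("droppath")
  m$rate <- rate
  m
}
nnForward.nn_droppath <- function(m, x, training = FALSE) {
  if (!training || m$rate <= 0) {
    m$cache <- NULL
    return(x)
  }
  d <- dim(x)
  keep <- as.numeric(stats::runif(d[3]) >= m$rate)
  s <- if (m$rate >= 1) keep * 0 else keep / (1 - m$rate)
  f <- rep(rep(s, each = d[1] * d[2]), times = d[4])
  m$cache <- f
  x * f
}
nnBackward.nn_droppath <- function(m, dy) {
  if (is.null(m$cache)) dy else dy * m$cache
}
nnDescribe.nn_droppath <- function(m, shp) list(rows = NULL, out = shp)

## ---- squeeze-and-excitation ------------------------------------------------

nnSE <- function(C, reduction = 16L) {
  m <- nnModule("se")
  m$C <- C
  m$Cr <- max(1L, C %/% reduction)
  if (!nnLazy()) {
    m$params <- list(
      W1 = matrix(stats::rnorm(C * m$Cr, 0, sqrt(2 / C)), C, m$Cr),
      b1 = numeric(m$Cr),
      W2 = matrix(stats::rnorm(m$Cr * C, 0, sqrt(2 / m$Cr)), m$Cr, C),
      b2 = numeric(C))
    m$decay <- c(W1 = TRUE, b1 = FALSE, W2 = TRUE, b2 = FALSE)
  }
  m
}

nnForward.nn_se <- function(m, x, training = FALSE) {
  d <- dim(x)
  P <- d[1] * d[2]
  p <- matrix(colMeans(matrix(x, P, d[3] * d[4])), d[3], d[4])
  h1 <- p %*% m$params$W1 + rep(m$params$b1, each = d[3])
  r <- pmax(h1, 0)
  z <- r %*% m$params$W2 + rep(m$params$b2, each = d[3])
  s <- 1 / (1 + exp(-z))
  f <- rep(as.vector(s), each = P)
  m$cache <- list(x = x, p = p, h1 = h1, r = r, s = s, d = d, f = f)
  x * f
}

nnBackward.nn_se <- function(m, dy) {
  cc <- m$cache
  d <- cc$d
  P <- d[1] * d[2]
  ds <- matrix(colSums(matrix(dy * cc$x, P, d[3] * d[4])), d[3], d[4])
  dz <- ds * cc$s * (1 - cc$s)
  m$grads$W2 <- m$grads$W2 + crossprod(cc$r, dz)
  m$grads$b2 <- m$grads$b2 + colSums(dz)
  dr <- tcrossprod(dz, m$params$W2)
  dh1 <- dr * (cc$h1 > 0)
  m$grads$W1 <- m$grads$W1 + crossprod(cc$p, dh1)
  m$grads$b1 <- m$grads$b1 + colSums(dh1)
  dp <- tcrossprod(dh1, m$params$W1)
  dy * cc$f + rep(as.vector(dp) / P, each = P)
}

nnDescribe.nn_se <- function(m, shp) {
  p <- m$C * m$Cr + m$Cr + m$Cr * m$C + m$C
  list(rows = descRow("se", p, 2 * m$C * m$Cr), out = shp)
}

## ---- sequential container --------------------------------------------------

nnSeq <- function(...) {
  m <- nnModule("seq")
  mods <- list(...)
  if (length(mods) == 1 && is.list(mods[[1]]) && !inherits(mods[[1]], "nn_module"))
    mods <- mods[[1]]
  m$children <- mods
  m
}
nnForward.nn_seq <- function(m, x, training = FALSE) {
  for (ch in m$children) x <- nnForward(ch, x, training)
  x
}
nnBackward.nn_seq <- function(m, dy) {
  for (ch in rev(m$children)) dy <- nnBackward(ch, dy)
  dy
}
nnDescribe.nn_seq <- function(m, shp) {
  rows <- NULL
  for (ch in m$children) {
    dd <- nnDescribe(ch, shp)
    rows <- rbind(rows, dd$rows)
    shp <- dd$out
  }
  list(rows = rows, out = shp)
}

## ---- parameter traversal & optimizer ---------------------------------------

nnModules <- function(m) {
  out <- list(m)
  for (ch in m$children) out <- c(out, nnModules(ch))
  out
}

nnParamRefs <- function(m) {
  refs <- list()
  for (mod in nnModules(m)) {
    if (!is.null(mod$params)) {
      for (nm in names(mod$params)) {
        refs[[length(refs) + 1L]] <-
          list(mod = mod, name = nm, decay = isTRUE(mod$decay[[nm]]))
      }
    }
  }
  refs
}

nnParamCount <- function(m) {
  sum(vapply(nnParamRefs(m), function(r) length(r$mod$params[[r$name]]), 0))
}

nnZeroGrads <- function(m) {
  for (mod in nnModules(m)) {
    if (!is.null(mod$params)) {
      mod$grads <- lapply(mod$params, function(p) p * 0)
    }
  }
  invisible(NULL)
}

nnAdamW <- function(refs, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                    weight_decay = 0.01) {
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  state$m <- lapply(refs, function(r) r$mod$params[[r$name]] * 0)
  state$v <- lapply(refs, function(r) r$mod$params[[r$name]] * 0)
  step <- function(lr_now = lr) {
    state$t <- state$t + 1L
    bc1 <- 1 - beta1^state$t
    bc2 <- 1 - beta2^state$t
    for (i in seq_along(refs)) {
      r <- refs[[i]]
      g <- r$mod$grads[[r$name]]
      state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
      state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
      mhat <- state$m[[i]] / bc1
      vhat <- state$v[[i]] / bc2
      p <- r$mod$params[[r$name]]
      if (r$decay && weight_decay > 0) p <- p - lr_now * weight_decay * p
      r$mod$params[[r$name]] <- p - lr_now * mhat / (sqrt(vhat) + eps)
    }
    invisible(NULL)
  }
  list(step = step, state = state)
}

## ---- (de)serialization of weights ------------------------------------------

nnGetState <- function(m) {
  mods <- nnModules(m)
  lapply(mods, function(mod) list(params = mod$params, buffers = mod$buffers))
}

nnSetState <- function(m, state) {
  mods <- nnModules(m)
  stopifnot(length(mods) == length(state))
  for (i in seq_along(mods)) {
    mods[[i]]$params <- state[[i]]$params
    mods[[i]]$buffers <- state[[i]]$buffers
  }
  invisible(m)
}

## ---- small helpers ---------------------------------------------------------

# promote a single (H, W, C) map or (H, W) matrix to a batched (H, W, 1, C)
nnBatch <- function(x) {
  d <- dim(x)
  if (length(d) == 2) array(x, c(d[1], d[2], 1L, 1L))
  else if (length(d) == 3) array(x, c(d[1], d[2], 1L, d[3]))
  else x
}

nnUnbatch <- function(x) {
  d <- dim(x)
  array(x[, , 1L, , drop = FALSE], c(d[1], d[2], d[4]))
}
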