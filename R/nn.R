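# Internal training engine for the residual convolutional regressor.
#
# Activations for a batch of B tiles with P positions and C channels are
# stored as a (B*P) x C matrix with row index (p-1)*B + b (batch-fastest
# within position), which lets 1-D convolution be expressed as an im2col
# gather of shifted row blocks followed by a single GEMM. Batch
# normalization is per channel over all B*P rows; all gradients are exact
# analytic backprop (verified against numerical differentiation in the test
# suite).

#' @noRd
.row_broadcast <- function(M, v) M + rep(v, each = nrow(M))

# ---- conv1d (same padding, odd kernel) --------------------------------------

#' @noRd
.conv_fwd <- function(X, W, b, k, B, P) {
  Cin <- ncol(X)
  pad <- (k - 1L) %/% 2L
  M <- matrix(0, B * P, k * Cin)
  for (j in seq_len(k)) {
    d <- j - 1L - pad
    ps <- max(1L, 1L - d); pe <- min(P, P - d)
    if (ps > pe) next
    dst <- ((ps - 1L) * B + 1L):(pe * B)
    M[dst, ((j - 1L) * Cin + 1L):(j * Cin)] <- X[dst + d * B, , drop = FALSE]
  }
  list(out = .row_broadcast(M %*% W, b), M = M)
}

#' @noRd
.conv_bwd <- function(dZ, cache, W, k, Cin, B, P) {
  pad <- (k - 1L) %/% 2L
  dW <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dM <- dZ %*% t(W)
  dX <- matrix(0, B * P, Cin)
  for (j in seq_len(k)) {
    d <- j - 1L - pad
    ps <- max(1L, 1L - d); pe <- min(P, P - d)
    if (ps > pe) next
    dst <- ((ps - 1L) * B + 1L):(pe * B)
    src <- dst + d * B
    dX[src, ] <- dX[src, ] + dM[dst, ((j - 1L) * Cin + 1L):(j * Cin), drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- batch norm -------------------------------------------------------------

#' @noRd
.bn_fwd <- function(X, g, beta, rm, rv, train, eps = 1e-5, momentum = 0.1) {
  n <- nrow(X)
  if (train) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = n)
    v <- colMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * rep(inv, each = n)
    list(out = .row_broadcast(xhat * rep(g, each = n), beta),
         xhat = xhat, inv = inv,
         rm = (1 - momentum) * rm + momentum * mu,
         rv = (1 - momentum) * rv + momentum * v)
  } else {
    inv <- 1 / sqrt(rv + eps)
    xhat <- (X - rep(rm, each = n)) * rep(inv, each = n)
    list(out = .row_broadcast(xhat * rep(g, each = n), beta))
  }
}

#' @noRd
.bn_bwd <- function(dY, cache, g) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = n)
  dg <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dX <- rep(cache$inv, each = n) *
    (dxhat - rep(m1, each = n) - xhat * rep(m2, each = n))
  list(dX = dX, dg = dg, dbeta = dbeta)
}

# ---- model ------------------------------------------------------------------

#' @noRd
.nn_init <- function(arch, seed) {
  .with_seed(seed, {
    C <- arch$channels
    he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
    params <- list(
      stem.W = matrix(he(arch$stem_kernel * arch$in_channels,
                         arch$stem_kernel * arch$in_channels * C),
                      arch$stem_kernel * arch$in_channels, C),
      stem.b = rep(0, C),
      bn0.g = rep(1, C), bn0.b = rep(0, C))
    for (i in seq_len(arch$n_blocks)) {
      nm <- function(s) sprintf("blk%d.%s", i, s)
      params[[nm("W1")]] <- matrix(he(arch$block_kernel * C,
                                      arch$block_kernel * C * C),
                                   arch$block_kernel * C, C)
      params[[nm("b1")]] <- rep(0, C)
      params[[nm("g1")]] <- rep(1, C); params[[nm("be1")]] <- rep(0, C)
      params[[nm("W2")]] <- matrix(he(arch$block_kernel * C,
                                      arch$block_kernel * C * C),
                                   arch$block_kernel * C, C)
      params[[nm("b2")]] <- rep(0, C)
      params[[nm("g2")]] <- rep(1, C); params[[nm("be2")]] <- rep(0, C)
    }
    params$head.w <- matrix(stats::rnorm(C, 0, sqrt(1 / C)), C, 1)
    params$head.b <- 0
    bn_names <- c("bn0", unlist(lapply(seq_len(arch$n_blocks), function(i)
      sprintf("blk%d.n%d", i, 1:2))))
    bn_state <- stats::setNames(
      lapply(bn_names, function(x) list(rm = rep(0, C), rv = rep(1, C))),
      bn_names)
    list(params = params, bn = bn_state)
  })
}

#' Forward pass. Returns prediction vector (z-scale) and caches for backward.
#' In train mode, updated running BN statistics are returned in `bn`.
#' @noRd
.nn_fwd <- function(model, X, B, P, train = FALSE) {
  p <- model$params; bn <- model$bn; a <- model$arch
  cache <- list()
  cv <- .conv_fwd(X, p$stem.W, p$stem.b, a$stem_kernel, B, P)
  nb <- .bn_fwd(cv$out, p$bn0.g, p$bn0.b, bn$bn0$rm, bn$bn0$rv, train)
  if (train) { bn$bn0$rm <- nb$rm; bn$bn0$rv <- nb$rv }
  H <- nb$out * (nb$out > 0)
  cache$stem <- list(cv = cv, nb = nb, pre = nb$out)
  cache$blocks <- vector("list", a$n_blocks)
  for (i in seq_len(a$n_blocks)) {
    nm <- function(s) sprintf("blk%d.%s", i, s)
    bn1 <- bn[[sprintf("blk%d.n1", i)]]; bn2 <- bn[[sprintf("blk%d.n2", i)]]
    c1 <- .conv_fwd(H, p[[nm("W1")]], p[[nm("b1")]], a$block_kernel, B, P)
    n1 <- .bn_fwd(c1$out, p[[nm("g1")]], p[[nm("be1")]], bn1$rm, bn1$rv, train)
    A1 <- n1$out * (n1$out > 0)
    c2 <- .conv_fwd(A1, p[[nm("W2")]], p[[nm("b2")]], a$block_kernel, B, P)
    n2 <- .bn_fwd(c2$out, p[[nm("g2")]], p[[nm("be2")]], bn2$rm, bn2$rv, train)
    S <- n2$out + H
    if (train) {
      bn[[sprintf("blk%d.n1", i)]] <- list(rm = n1$rm, rv = n1$rv)
      bn[[sprintf("blk%d.n2", i)]] <- list(rm = n2$rm, rv = n2$rv)
    }
    cache$blocks[[i]] <- list(Hin = H, c1 = c1, n1 = n1, pre1 = n1$out,
                              A1 = A1, c2 = c2, n2 = n2, S = S)
    H <- S * (S > 0)
  }
  G <- rowsum(H, group = rep(seq_len(B), times = P), reorder = TRUE) / P
  yhat <- as.vector(G %*% p$head.w) + p$head.b
  cache$H <- H; cache$G <- G
  list(yhat = yhat, cache = cache, bn = bn)
}

#' Backward pass: gradient of mean((yhat - y)^2) w.r.t. all parameters.
#' @noRd
.nn_bwd <- function(model, X, B, P, fwd, y) {
  p <- model$params; a <- model$arch
  cache <- fwd$cache
  grads <- list()
  dy <- 2 * (fwd$yhat - y) / B
  grads$head.w <- crossprod(cache$G, dy)
  grads$head.b <- sum(dy)
  dG <- dy %*% t(p$head.w)            # B x C
  dH <- dG[rep(seq_len(B), times = P), , drop = FALSE] / P
  for (i in rev(seq_len(a$n_blocks))) {
    nm <- function(s) sprintf("blk%d.%s", i, s)
    bk <- cache$blocks[[i]]
    dS <- dH * (bk$S > 0)
    b2 <- .bn_bwd(dS, bk$n2, p[[nm("g2")]])
    grads[[nm("g2")]] <- b2$dg; grads[[nm("be2")]] <- b2$dbeta
    cv2 <- .conv_bwd(b2$dX, bk$c2, p[[nm("W2")]], a$block_kernel,
                     ncol(bk$A1), B, P)
    grads[[nm("W2")]] <- cv2$dW; grads[[nm("b2")]] <- cv2$db
    dA1 <- cv2$dX * (bk$pre1 > 0)
    b1 <- .bn_bwd(dA1, bk$n1, p[[nm("g1")]])
    grads[[nm("g1")]] <- b1$dg; grads[[nm("be1")]] <- b1$dbeta
    cv1 <- .conv_bwd(b1$dX, bk$c1, p[[nm("W1")]], a$block_kernel,
                     ncol(bk$Hin), B, P)
    grads[[nm("W1")]] <- cv1$dW; grads[[nm("b1")]] <- cv1$db
    dH <- cv1$dX + dS                 # skip connection
  }
  dR0 <- dH * (cache$stem$pre > 0)
  b0 <- .bn_bwd(dR0, cache$stem$nb, p$bn0.g)
  grads$bn0.g <- b0$dg; grads$bn0.b <- b0$dbeta
  cv0 <- .conv_bwd(b0$dX, cache$stem$cv, p$stem.W, a$stem_kernel,
                   a$in_channels, B, P)
  grads$stem.W <- cv0$dW; grads$stem.b <- cv0$db
  grads
}

# ---- Adam -------------------------------------------------------------------

#' @noRd
.adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

#' @noRd
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- batched prediction on the z scale --------------------------------------

#' @noRd
.nn_predict_z <- function(model, x_array, chunk = 512L) {
  n <- dim(x_array)[1]; P <- dim(x_array)[2]; C <- dim(x_array)[3]
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    B <- length(idx)
    X <- matrix(x_array[idx, , , drop = FALSE], B * P, C)
    out[idx] <- .nn_fwd(model, X, B, P, train = FALSE)$yhat
  }
  out
}
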