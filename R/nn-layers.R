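# Neural-network primitives on (B*H*W) x C feature matrices. Pixel rows are
# row-major within each sample, samples stacked; convolutions reduce to
# GEMMs on im2col patches (see src/kernels.cpp).

nn_linear_fwd <- function(X, W, b) {
  sweep2(X %*% W, b)
}

sweep2 <- function(M, b) {
  # add a row vector to every row without forming an index matrix
  M + rep(b, each = nrow(M))
}

nn_linear_bwd <- function(X, W, dY) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

nn_conv_fwd <- function(X, W, b, B, H, Wd) {
  P <- im2col3(X, B, H, Wd)
  list(y = sweep2(P %*% W, b), P = P)
}

nn_conv_bwd <- function(P, W, dY, B, H, Wd, C_in) {
  dP <- dY %*% t(W)
  list(dX = col2im3(dP, B, H, Wd, C_in),
       dW = crossprod(P, dY), db = colSums(dY))
}

nn_bn_fwd <- function(X, gamma, beta, state, training, momentum = 0.9,
                      eps = 1e-5) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    Xc <- X - rep(mu, each = n)
    v <- colMeans(Xc * Xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- Xc * rep(inv, each = n)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    inv <- 1 / sqrt(state$var + eps)
    xhat <- (X - rep(state$mean, each = n)) * rep(inv, each = n)
  }
  list(y = xhat * rep(gamma, each = n) + rep(beta, each = n),
       xhat = xhat, inv = inv, state = state)
}

nn_bn_bwd <- function(cache, gamma, dY) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = n)
  dX <- rep(cache$inv, each = n) *
    (dxhat - rep(colMeans(dxhat), each = n) -
       cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

nn_relu_fwd <- function(X) {
  mask <- X > 0
  list(y = X * mask, mask = mask)
}

nn_relu_bwd <- function(mask, dY) dY * mask

# 2x2 stride-2 transposed convolution: each input pixel emits a 2x2 output
# block. Index vectors map input rows to the four output sub-lattices.
tconv_idx <- function(B, h, w) {
  n0 <- 0:(B * h * w - 1L)
  b <- n0 %/% (h * w)
  r <- (n0 %% (h * w)) %/% w
  q <- n0 %% w
  base <- (b * 2L * h + 2L * r) * 2L * w + 2L * q
  list(base + 1L, base + 2L, base + 2L * w + 1L, base + 2L * w + 2L)
}

nn_tconv_fwd <- function(X, W, b, B, h, w) {
  # W: array (C_in, C_out, 4)
  idx <- tconv_idx(B, h, w)
  Y <- matrix(0, 4L * nrow(X), dim(W)[2])
  for (k in 1:4) Y[idx[[k]], ] <- X %*% W[, , k]
  list(y = sweep2(Y, b), idx = idx)
}

nn_tconv_bwd <- function(X, W, idx, dY) {
  dW <- array(0, dim(W))
  dX <- matrix(0, nrow(X), dim(W)[1])
  for (k in 1:4) {
    g <- dY[idx[[k]], , drop = FALSE]
    dW[, , k] <- crossprod(X, g)
    dX <- dX + g %*% t(W[, , k])
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

nn_pool_fwd <- function(X, B, H, Wd) {
  out <- maxpool2(X, B, H, Wd)
  list(y = out$y, argmax = out$argmax, n_in = nrow(X))
}

nn_pool_bwd <- function(cache, dY) {
  maxpool2_bwd(dY, cache$argmax, cache$n_in)
}

# -- parameter tree helpers --------------------------------------------------

params_count <- function(params) {
  sum(vapply(params, function(unit) {
    sum(vapply(unit, length, integer(1)))
  }, integer(1)))
}

params_zero_like <- function(params) {
  lapply(params, function(unit) lapply(unit, function(a) a * 0))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (u in names(params)) {
    for (p in names(params[[u]])) {
      g <- grads[[u]][[p]]
      if (is.null(g)) next
      state$m[[u]][[p]] <- beta1 * state$m[[u]][[p]] + (1 - beta1) * g
      state$v[[u]][[p]] <- beta2 * state$v[[u]][[p]] + (1 - beta2) * g * g
      params[[u]][[p]] <- params[[u]][[p]] -
        lr * (state$m[[u]][[p]] / c1) / (sqrt(state$v[[u]][[p]] / c2) + eps)
    }
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  list(m = params_zero_like(params), v = params_zero_like(params), t = 0L)
}

staircase_lr <- function(lr0, decay_rate, decay_every, step) {
  lr0 * decay_rate^(step %/% decay_every)
}
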