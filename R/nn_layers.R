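# Internal neural-network engine.
#
# Activations flow as 3-D arrays [batch, time, channels] through the
# convolutional stage and as matrices [batch, features] through dense
# stages. Each layer is a plain list (type, name, params, config); forward
# returns (out, cache), backward consumes (cache, dout) and returns dx plus
# per-parameter gradients. Gradients are hand-derived; every layer is
# finite-difference tested.
#
# Design notes:
# * Batch-norm uses batch statistics in training and running statistics
#   (momentum 0.9, eps 1e-3) at inference.
# * The capsule layer's backward pass treats the routing coefficients c_ij
#   as constants (gradients flow through s_j = sum_i c_ij u_hat only), a
#   standard simplification; its forward pass is the exact routing loop.
# * Dropout is inverted (scaling at train time), so inference is identity.

new_layer <- function(type, name, params = list(), config = list()) {
  list(type = type, name = name, params = params, config = config)
}

lecun_init <- function(rng, nrow, ncol, fan_in = nrow) {
  matrix(rng_rnorm(rng, nrow * ncol, sd = 1 / sqrt(fan_in)), nrow, ncol)
}

## ---- conv1d (kernel 3, length-preserving "same" padding) ----

layer_conv1d <- function(rng, name, c_in, c_out, kernel = 3) {
  new_layer("conv1d", name,
            params = list(W = lecun_init(rng, kernel * c_in, c_out),
                          b = rep(0, c_out)),
            config = list(c_in = c_in, c_out = c_out, kernel = kernel))
}

conv1d_im2col <- function(X, kernel) {
  n <- dim(X)[1]; t <- dim(X)[2]; c <- dim(X)[3]
  pad <- (kernel - 1) %/% 2
  Xp <- array(0, c(n, t + 2 * pad, c))
  Xp[, (pad + 1):(pad + t), ] <- X
  cols <- vector("list", kernel)
  for (k in seq_len(kernel)) {
    cols[[k]] <- matrix(Xp[, k:(k + t - 1), , drop = FALSE], n * t, c)
  }
  do.call(cbind, cols)
}

forward_conv1d <- function(layer, X, training, rng) {
  n <- dim(X)[1]; t <- dim(X)[2]
  Xc <- conv1d_im2col(X, layer$config$kernel)
  out_m <- sweep(Xc %*% layer$params$W, 2, layer$params$b, "+")
  list(out = array(out_m, c(n, t, layer$config$c_out)),
       cache = list(Xc = Xc, n = n, t = t))
}

backward_conv1d <- function(layer, cache, dout) {
  n <- cache$n; t <- cache$t
  kern <- layer$config$kernel; c_in <- layer$config$c_in
  pad <- (kern - 1) %/% 2
  dm <- matrix(dout, n * t, layer$config$c_out)
  dW <- crossprod(cache$Xc, dm)
  db <- colSums(dm)
  dXc <- tcrossprod(dm, layer$params$W)
  dXp <- array(0, c(n, t + 2 * pad, c_in))
  for (k in seq_len(kern)) {
    cols <- ((k - 1) * c_in + 1):(k * c_in)
    dXp[, k:(k + t - 1), ] <- dXp[, k:(k + t - 1), , drop = FALSE] +
      array(dXc[, cols], c(n, t, c_in))
  }
  list(dx = dXp[, (pad + 1):(pad + t), , drop = FALSE],
       grads = list(W = dW, b = db))
}

## ---- batch normalisation (per channel or per feature) ----

layer_batchnorm <- function(name, width, momentum = 0.9, epsilon = 1e-3) {
  new_layer("batchnorm", name,
            params = list(gamma = rep(1, width), beta = rep(0, width)),
            config = list(width = width, momentum = momentum,
                          epsilon = epsilon,
                          running_mean = rep(0, width),
                          running_var = rep(1, width)))
}

forward_batchnorm <- function(layer, X, training, rng) {
  dims <- dim(X)
  conv_mode <- length(dims) == 3
  Xm <- if (conv_mode) matrix(X, dims[1] * dims[2], dims[3]) else X
  eps <- layer$config$epsilon
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(sweep(Xm, 2, mu)^2)
  } else {
    mu <- layer$config$running_mean
    v <- layer$config$running_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(Xm, 2, mu), 2, ivar, "*")
  out_m <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2,
                 layer$params$beta, "+")
  out <- if (conv_mode) array(out_m, dims) else out_m
  state_update <- NULL
  if (training) {
    mom <- layer$config$momentum
    state_update <- list(
      running_mean = mom * layer$config$running_mean + (1 - mom) * mu,
      running_var = mom * layer$config$running_var + (1 - mom) * v)
  }
  list(out = out,
       cache = list(xhat = xhat, ivar = ivar, dims = dims,
                    conv_mode = conv_mode),
       state_update = state_update)
}

backward_batchnorm <- function(layer, cache, dout) {
  dm <- if (cache$conv_mode) {
    matrix(dout, cache$dims[1] * cache$dims[2], cache$dims[3])
  } else dout
  m <- nrow(dm)
  xhat <- cache$xhat
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, layer$params$gamma, "*")
  dx <- sweep(
    dxhat - matrix(colMeans(dxhat), m, ncol(dm), byrow = TRUE) -
      xhat * matrix(colMeans(dxhat * xhat), m, ncol(dm), byrow = TRUE),
    2, cache$ivar, "*")
  if (cache$conv_mode) dx <- array(dx, cache$dims)
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- SELU activation ----

layer_selu <- function(name) new_layer("selu", name)

forward_selu <- function(layer, X, training, rng) {
  list(out = selu_keep_shape(X), cache = list(x = X))
}

selu_keep_shape <- function(X) {
  out <- selu(X)
  dim(out) <- dim(X)
  out
}

backward_selu <- function(layer, cache, dout) {
  g <- selu_grad(cache$x)
  dim(g) <- dim(cache$x)
  list(dx = dout * g, grads = list())
}

## ---- max pooling (size 2, stride 2, floor) ----

layer_maxpool <- function(name) new_layer("maxpool", name)

forward_maxpool <- function(layer, X, training, rng) {
  t <- dim(X)[2]
  t_out <- t %/% 2L
  a <- X[, seq(1, 2 * t_out, by = 2), , drop = FALSE]
  b <- X[, seq(2, 2 * t_out, by = 2), , drop = FALSE]
  mask <- a >= b
  list(out = pmax(a, b) * 1,
       cache = list(mask = mask, t_in = t, dims_in = dim(X)))
}

backward_maxpool <- function(layer, cache, dout) {
  dx <- array(0, cache$dims_in)
  t_out <- dim(dout)[2]
  dx[, seq(1, 2 * t_out, by = 2), ] <- dout * cache$mask
  dx[, seq(2, 2 * t_out, by = 2), ] <- dout * !cache$mask
  list(dx = dx, grads = list())
}

## ---- dropout (inverted) ----

layer_dropout <- function(name, p) {
  new_layer("dropout", name, config = list(p = p))
}

forward_dropout <- function(layer, X, training, rng) {
  p <- layer$config$p
  if (!training || p <= 0) {
    return(list(out = X, cache = list(mask = NULL)))
  }
  keep <- array(rng_runif(rng, length(X)) >= p, dim(X) %||% length(X))
  mask <- keep / (1 - p)
  list(out = X * mask, cache = list(mask = mask))
}

backward_dropout <- function(layer, cache, dout) {
  dx <- if (is.null(cache$mask)) dout else dout * cache$mask
  list(dx = dx, grads = list())
}

## ---- global max pool over time: [n,t,c] -> [n,c] ----

layer_gmaxpool <- function(name) new_layer("gmaxpool", name)

forward_gmaxpool <- function(layer, X, training, rng) {
  n <- dim(X)[1]; t <- dim(X)[2]; c <- dim(X)[3]
  if (t == 1L) {
    out <- matrix(X[, 1, ], n, c)
    idx <- matrix(1L, n, c)
  } else {
    out <- apply(X, c(1, 3), max)
    idx <- apply(X, c(1, 3), which.max)
  }
  list(out = out, cache = list(idx = idx, dims_in = dim(X)))
}

backward_gmaxpool <- function(layer, cache, dout) {
  n <- cache$dims_in[1]; t <- cache$dims_in[2]; c <- cache$dims_in[3]
  dx <- array(0, cache$dims_in)
  lin <- rep(seq_len(n), c) + (as.vector(cache$idx) - 1L) * n +
    rep((seq_len(c) - 1L) * n * t, each = n)
  dx[lin] <- as.vector(dout)
  list(dx = dx, grads = list())
}

## ---- mean pool over time: [n,t,c] -> [n,c] ----

layer_tmeanpool <- function(name) new_layer("tmeanpool", name)

forward_tmeanpool <- function(layer, X, training, rng) {
  n <- dim(X)[1]; t <- dim(X)[2]; c <- dim(X)[3]
  out <- matrix(0, n, c)
  for (p in seq_len(t)) out <- out + matrix(X[, p, ], n, c)
  list(out = out / t, cache = list(dims_in = dim(X)))
}

backward_tmeanpool <- function(layer, cache, dout) {
  t <- cache$dims_in[2]
  dx <- array(0, cache$dims_in)
  for (p in seq_len(t)) dx[, p, ] <- dout / t
  list(dx = dx, grads = list())
}

## ---- dense ----

layer_dense <- function(rng, name, d_in, d_out) {
  new_layer("dense", name,
            params = list(W = lecun_init(rng, d_in, d_out), b = rep(0, d_out)),
            config = list(d_in = d_in, d_out = d_out))
}

forward_dense <- function(layer, X, training, rng) {
  list(out = sweep(X %*% layer$params$W, 2, layer$params$b, "+"),
       cache = list(X = X))
}

backward_dense <- function(layer, cache, dout) {
  list(dx = tcrossprod(dout, layer$params$W),
       grads = list(W = crossprod(cache$X, dout), b = colSums(dout)))
}

## ---- capsule head layer ----
# [n,t,c] -> primary capsules (width d_in) -> squash -> u_hat = u W ->
# dynamic routing (r iterations) -> output-capsule lengths [n, n_out]

layer_capsule <- function(rng, name, t, c, n_out, d_in = 16, d_out = 16,
                          r = 3) {
  total <- t * c
  if (total %% d_in != 0) {
    stop("feature map t*channels = ", total,
         " is not divisible by primary capsule width d_in = ", d_in)
  }
  n_in <- total %/% d_in
  W <- array(rng_rnorm(rng, n_in * n_out * d_in * d_out,
                       sd = 1 / sqrt(d_in)),
             c(n_in, n_out, d_in, d_out))
  new_layer("capsule", name, params = list(W = W),
            config = list(t = t, c = c, n_in = n_in, n_out = n_out,
                          d_in = d_in, d_out = d_out, r = r))
}

# [n,t,c] -> [n, d_in, n_in] with time-major flattening (matches
# capsule_head(): capsule i takes d_in consecutive flattened values)
caps_reshape_in <- function(X, d_in) {
  n <- dim(X)[1]; t <- dim(X)[2]; c <- dim(X)[3]
  Xp <- aperm(X, c(1, 3, 2))           # [n, c, t]
  array(matrix(Xp, n, c * t), c(n, d_in, (c * t) %/% d_in))
}

caps_reshape_back <- function(dU, t, c) {
  n <- dim(dU)[1]
  Xp <- array(matrix(dU, n, c * t), c(n, c, t))
  aperm(Xp, c(1, 3, 2))
}

# squash each [d]-vector of an [n, d, k] array
squash_array <- function(A, epsilon = 1e-7) {
  n2 <- apply(A^2, c(1, 3), sum)                       # [n, k]
  scale <- n2 / (1 + n2) / sqrt(n2 + epsilon^2)
  A * aperm(array(scale, c(dim(A)[1], dim(A)[3], dim(A)[2])), c(1, 3, 2))
}

forward_capsule <- function(layer, X, training, rng) {
  cfg <- layer$config
  n <- dim(X)[1]
  U_raw <- caps_reshape_in(X, cfg$d_in)                # [n, d_in, n_in]
  U <- squash_array(U_raw)
  W <- layer$params$W
  Uhat <- array(0, c(n, cfg$d_out, cfg$n_in, cfg$n_out))
  for (i in seq_len(cfg$n_in)) {
    Ui <- matrix(U[, , i], n, cfg$d_in)
    for (j in seq_len(cfg$n_out)) {
      Uhat[, , i, j] <- Ui %*% W[i, j, , ]
    }
  }
  # dynamic routing (batched over samples)
  b_log <- array(0, c(n, cfg$n_in, cfg$n_out))
  v <- array(0, c(n, cfg$d_out, cfg$n_out))
  cc <- NULL
  s <- array(0, c(n, cfg$d_out, cfg$n_out))
  for (it in seq_len(cfg$r)) {
    bmax <- apply(b_log, c(1, 2), max)
    e <- exp(b_log - array(bmax, dim(b_log)))
    cc <- e / array(apply(e, c(1, 2), sum), dim(e))
    for (j in seq_len(cfg$n_out)) {
      sj <- matrix(0, n, cfg$d_out)
      for (i in seq_len(cfg$n_in)) {
        sj <- sj + matrix(Uhat[, , i, j], n, cfg$d_out) * cc[, i, j]
      }
      s[, , j] <- sj
      v[, , j] <- squash(sj)
    }
    for (j in seq_len(cfg$n_out)) {
      vj <- matrix(v[, , j], n, cfg$d_out)
      for (i in seq_len(cfg$n_in)) {
        b_log[, i, j] <- b_log[, i, j] +
          rowSums(matrix(Uhat[, , i, j], n, cfg$d_out) * vj)
      }
    }
  }
  lens <- sqrt(apply(v^2, c(1, 3), sum))               # [n, n_out]
  list(out = lens,
       cache = list(U_raw = U_raw, U = U, Uhat = Uhat, cc = cc, s = s,
                    v = v, lens = lens, n = n))
}

backward_capsule <- function(layer, cache, dout) {
  cfg <- layer$config
  n <- cache$n
  W <- layer$params$W
  dW <- array(0, dim(W))
  dU <- array(0, dim(cache$U))
  for (j in seq_len(cfg$n_out)) {
    vj <- matrix(cache$v[, , j], n, cfg$d_out)
    lj <- cache$lens[, j]
    dvj <- vj * (dout[, j] / pmax(lj, 1e-12))
    dsj <- squash_backward(matrix(cache$s[, , j], n, cfg$d_out), dvj)
    for (i in seq_len(cfg$n_in)) {
      dUhat_ij <- dsj * cache$cc[, i, j]               # c_ij detached
      Ui <- matrix(cache$U[, , i], n, cfg$d_in)
      dW[i, j, , ] <- dW[i, j, , ] + crossprod(Ui, dUhat_ij)
      dU[, , i] <- dU[, , i] + tcrossprod(dUhat_ij, W[i, j, , ])
    }
  }
  dU_raw <- array(0, dim(dU))
  for (i in seq_len(cfg$n_in)) {
    dU_raw[, , i] <- squash_backward(matrix(cache$U_raw[, , i], n, cfg$d_in),
                                     matrix(dU[, , i], n, cfg$d_in))
  }
  list(dx = caps_reshape_back(dU_raw, cfg$t, cfg$c), grads = list(W = dW))
}

## ---- transformer encoder block ----

layer_tfblock <- function(rng, name, d_model, n_heads, mlp_ratio = 4) {
  if (d_model %% n_heads != 0) {
    stop("d_model (", d_model, ") not divisible by n_heads (", n_heads, ")")
  }
  d_ff <- mlp_ratio * d_model
  new_layer("tfblock", name,
            params = list(
              Wq = lecun_init(rng, d_model, d_model), bq = rep(0, d_model),
              Wk = lecun_init(rng, d_model, d_model), bk = rep(0, d_model),
              Wv = lecun_init(rng, d_model, d_model), bv = rep(0, d_model),
              Wo = lecun_init(rng, d_model, d_model), bo = rep(0, d_model),
              W1 = lecun_init(rng, d_model, d_ff), b1 = rep(0, d_ff),
              W2 = lecun_init(rng, d_ff, d_model), b2 = rep(0, d_model),
              ln1_gamma = rep(1, d_model), ln1_beta = rep(0, d_model),
              ln2_gamma = rep(1, d_model), ln2_beta = rep(0, d_model)),
            config = list(d_model = d_model, n_heads = n_heads,
                          d_ff = d_ff, epsilon = 1e-7))
}

ln_forward <- function(X, gamma, beta, eps) {
  m <- rowMeans(X)
  xc <- X - m
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  list(out = sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+"),
       xhat = xhat, istd = istd)
}

ln_backward <- function(cache, gamma, dout) {
  dxhat <- sweep(dout, 2, gamma, "*")
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dx <- (dxhat - rowMeans(dxhat) -
           cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$istd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

forward_tfblock <- function(layer, X, training, rng) {
  p <- layer$params; cfg <- layer$config
  n <- dim(X)[1]; t <- dim(X)[2]; d <- cfg$d_model
  h <- cfg$n_heads; dk <- d %/% h
  Xm <- matrix(X, n * t, d)                  # row = (sample, position)
  Q <- sweep(Xm %*% p$Wq, 2, p$bq, "+")
  K <- sweep(Xm %*% p$Wk, 2, p$bk, "+")
  V <- sweep(Xm %*% p$Wv, 2, p$bv, "+")
  O <- matrix(0, n * t, d)
  A_all <- array(0, c(n, h, t, t))
  for (b in seq_len(n)) {
    rows <- b + (seq_len(t) - 1L) * n
    for (head in seq_len(h)) {
      cols <- ((head - 1) * dk + 1):(head * dk)
      Qh <- Q[rows, cols, drop = FALSE]
      Kh <- K[rows, cols, drop = FALSE]
      S <- tcrossprod(Qh, Kh) / sqrt(dk)
      A <- exp(S - apply(S, 1, max))
      A <- A / rowSums(A)
      A_all[b, head, , ] <- A
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
    }
  }
  mha <- sweep(O %*% p$Wo, 2, p$bo, "+")
  res1 <- Xm + mha
  ln1 <- ln_forward(res1, p$ln1_gamma, p$ln1_beta, cfg$epsilon)
  a <- ln1$out
  H_pre <- sweep(a %*% p$W1, 2, p$b1, "+")
  H <- selu(H_pre)
  m2 <- sweep(H %*% p$W2, 2, p$b2, "+")
  res2 <- a + m2
  ln2 <- ln_forward(res2, p$ln2_gamma, p$ln2_beta, cfg$epsilon)
  list(out = array(ln2$out, c(n, t, d)),
       cache = list(Xm = Xm, Q = Q, K = K, V = V, O = O, A_all = A_all,
                    ln1 = ln1, a = a, H_pre = H_pre, H = H, ln2 = ln2,
                    n = n, t = t))
}

backward_tfblock <- function(layer, cache, dout) {
  p <- layer$params; cfg <- layer$config
  n <- cache$n; t <- cache$t; d <- cfg$d_model
  h <- cfg$n_heads; dk <- d %/% h
  dm <- matrix(dout, n * t, d)

  l2 <- ln_backward(cache$ln2, p$ln2_gamma, dm)
  dres2 <- l2$dx
  dW2 <- crossprod(cache$H, dres2)
  db2 <- colSums(dres2)
  dH <- tcrossprod(dres2, p$W2) * selu_grad(cache$H_pre)
  dW1 <- crossprod(cache$a, dH)
  db1 <- colSums(dH)
  da <- dres2 + tcrossprod(dH, p$W1)

  l1 <- ln_backward(cache$ln1, p$ln1_gamma, da)
  dres1 <- l1$dx
  dWo <- crossprod(cache$O, dres1)
  dbo <- colSums(dres1)
  dO <- tcrossprod(dres1, p$Wo)

  dQ <- matrix(0, n * t, d)
  dK <- matrix(0, n * t, d)
  dV <- matrix(0, n * t, d)
  for (b in seq_len(n)) {
    rows <- b + (seq_len(t) - 1L) * n
    for (head in seq_len(h)) {
      cols <- ((head - 1) * dk + 1):(head * dk)
      A <- matrix(cache$A_all[b, head, , ], t, t)
      dOh <- dO[rows, cols, drop = FALSE]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[rows, cols] <- dV[rows, cols] + crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A)) / sqrt(dk)
      dQ[rows, cols] <- dQ[rows, cols] +
        dS %*% cache$K[rows, cols, drop = FALSE]
      dK[rows, cols] <- dK[rows, cols] +
        crossprod(dS, cache$Q[rows, cols, drop = FALSE])
    }
  }
  Xm <- cache$Xm
  grads <- list(
    Wq = crossprod(Xm, dQ), bq = colSums(dQ),
    Wk = crossprod(Xm, dK), bk = colSums(dK),
    Wv = crossprod(Xm, dV), bv = colSums(dV),
    Wo = dWo, bo = dbo, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
    ln1_gamma = l1$dgamma, ln1_beta = l1$dbeta,
    ln2_gamma = l2$dgamma, ln2_beta = l2$dbeta)
  dXm <- dres1 + tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) +
    tcrossprod(dV, p$Wv)
  list(dx = array(dXm, c(n, t, d)), grads = grads)
}

## ---- dispatch ----

layer_forward <- function(layer, X, training = FALSE, rng = NULL) {
  switch(layer$type,
    conv1d = forward_conv1d(layer, X, training, rng),
    batchnorm = forward_batchnorm(layer, X, training, rng),
    selu = forward_selu(layer, X, training, rng),
    maxpool = forward_maxpool(layer, X, training, rng),
    dropout = forward_dropout(layer, X, training, rng),
    gmaxpool = forward_gmaxpool(layer, X, training, rng),
    tmeanpool = forward_tmeanpool(layer, X, training, rng),
    dense = forward_dense(layer, X, training, rng),
    capsule = forward_capsule(layer, X, training, rng),
    tfblock = forward_tfblock(layer, X, training, rng),
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv1d = backward_conv1d(layer, cache, dout),
    batchnorm = backward_batchnorm(layer, cache, dout),
    selu = backward_selu(layer, cache, dout),
    maxpool = backward_maxpool(layer, cache, dout),
    dropout = backward_dropout(layer, cache, dout),
    gmaxpool = backward_gmaxpool(layer, cache, dout),
    tmeanpool = backward_tmeanpool(layer, cache, dout),
    dense = backward_dense(layer, cache, dout),
    capsule = backward_capsule(layer, cache, dout),
    tfblock = backward_tfblock(layer, cache, dout),
    stop("unknown layer type: ", layer$type))
}

## ---- softmax cross-entropy ----

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

# y: integer class indices 1..K; returns mean loss, probs, dlogits
softmax_ce <- function(logits, y) {
  n <- nrow(logits)
  probs <- softmax_rows(logits)
  picked <- probs[cbind(seq_len(n), y)]
  loss <- -mean(log(pmax(picked, 1e-300)))
  dlogits <- probs
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, probs = probs, dlogits = dlogits / n)
}

# margin loss on capsule lengths (optional alternative to softmax CE)
margin_loss <- function(lengths, y, m_pos = 0.9, m_neg = 0.1, lambda = 0.5) {
  n <- nrow(lengths)
  T_c <- matrix(0, n, ncol(lengths))
  T_c[cbind(seq_len(n), y)] <- 1
  pos <- pmax(0, m_pos - lengths)
  neg <- pmax(0, lengths - m_neg)
  loss <- mean(rowSums(T_c * pos^2 + lambda * (1 - T_c) * neg^2))
  dl <- (T_c * (-2 * pos) + lambda * (1 - T_c) * 2 * neg) / n
  list(loss = loss, dlogits = dl, probs = softmax_rows(lengths))
}

## ---- Adam optimiser ----

adam_init <- function(layers) {
  states <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    ps <- layers[[li]]$params
    if (length(ps)) {
      states[[li]] <- lapply(ps, function(p) {
        list(m = array(0, dim(p) %||% length(p)),
             v = array(0, dim(p) %||% length(p)))
      })
    }
  }
  list(states = states, t = 0L)
}

adam_step <- function(layers, grads_by_layer, opt, lr = 0.001,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (li in seq_along(layers)) {
    gs <- grads_by_layer[[li]]
    if (is.null(gs) || !length(gs)) next
    for (pn in names(gs)) {
      st <- opt$states[[li]][[pn]]
      g <- gs[[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      upd <- lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      layers[[li]]$params[[pn]] <- layers[[li]]$params[[pn]] - upd
      opt$states[[li]][[pn]] <- st
    }
  }
  list(layers = layers, opt = opt)
}
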