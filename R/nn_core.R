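#' Constants of the scaled exponential linear unit
#'
#' The self-normalising pair: scale `lambda ~ 1.0507` and negative-branch
#' coefficient `alpha ~ 1.67326` (values from the self-normalising-network
#' derivation, quoted to the precision used throughout the field).
#' @export
selu_constants <- list(lambda = 1.0507009873554804934193349852946,
                       alpha = 1.6732632423543772848170429916717)

#' Scaled exponential linear unit
#'
#' `SELU(x) = lambda * x` for `x > 0` and
#' `lambda * alpha * (exp(x) - 1)` for `x <= 0`. Linear on the positive
#' branch, exponentially saturating at `-lambda * alpha` on the negative
#' branch; with suitable initialisation this keeps activations approximately
#' zero-mean/unit-variance across layers.
#'
#' @param x numeric vector/matrix/array (finite).
#' @return Same shape as `x`.
#' @examples
#' selu(1)      # lambda
#' selu(0)      # 0
#' -selu(-40) / selu_constants$lambda  # ~ alpha
#' @export
selu <- function(x) {
  l <- selu_constants$lambda
  a <- selu_constants$alpha
  out <- x
  pos <- x > 0
  out[pos] <- l * x[pos]
  out[!pos] <- l * a * expm1(x[!pos])
  out
}

# derivative of SELU w.r.t. its input (used by the training engine)
selu_grad <- function(x) {
  l <- selu_constants$lambda
  a <- selu_constants$alpha
  ifelse(x > 0, l, l * a * exp(x))
}

#' Batch normalisation transform
#'
#' `BN(x, gamma, beta) = beta + gamma * (x - E[X]) / sqrt(Var[X] + eps)`,
#' applied per feature.
#'
#' @param x numeric matrix `[n x features]` (a vector is treated as one
#'   feature column... no: as a single-row batch of features).
#' @param p list with `gamma`, `beta` (scalars or per-feature vectors),
#'   `mean`, `var` (per-feature statistics; if `NULL`, batch statistics of
#'   `x` are used), and `epsilon`.
#' @return Matrix of the same shape.
#' @export
batch_norm <- function(x, p) {
  x <- as.matrix(x)
  eps <- p$epsilon %||% 1e-3
  m <- p$mean %||% colMeans(x)
  v <- p$var %||% colMeans(sweep(x, 2, colMeans(x))^2)
  if (any(v < 0)) stop("variance must be >= 0")
  xhat <- sweep(sweep(x, 2, m), 2, sqrt(v + eps), "/")
  sweep(sweep(xhat, 2, p$gamma %||% 1, "*"), 2, p$beta %||% 0, "+")
}

#' Squash nonlinearity for capsule vectors
#'
#' Maps a vector `s` to `(|s|^2 / (1 + |s|^2)) * s / |s|`: direction
#' preserved, norm compressed into [0, 1). The zero vector maps to zero.
#'
#' @param s numeric vector, or a matrix whose rows are vectors.
#' @param epsilon stabiliser in the norm denominator.
#' @return Same shape as `s`.
#' @export
squash <- function(s, epsilon = 1e-7) {
  if (is.matrix(s)) {
    n2 <- rowSums(s^2)
    scale <- n2 / (1 + n2) / sqrt(n2 + epsilon^2)
    s * scale
  } else {
    n2 <- sum(s^2)
    s * (n2 / (1 + n2) / sqrt(n2 + epsilon^2))
  }
}

# d(squash)/ds backward: given s (matrix rows) and upstream dv, return ds.
# v = g(n) s with g(n) = n/(1+n^2) => J = g I + (g'/n) s s^T,
# g'(n) = (1 - n^2)/(1 + n^2)^2, handled smoothly at n ~ 0.
squash_backward <- function(s, dv, epsilon = 1e-7) {
  n2 <- rowSums(s^2)
  n <- sqrt(n2 + epsilon^2)
  g <- n / (1 + n2)
  gp <- (1 - n2) / (1 + n2)^2
  sv <- rowSums(s * dv)
  dv * g + s * (gp / n) * sv
}

#' Dynamic routing-by-agreement
#'
#' The iterative routing procedure coupling lower capsules i to upper
#' capsules j. Logits `b` start at zero; each iteration computes coupling
#' coefficients `c_ij = exp(b_ij) / sum_k exp(b_ik)` (softmax over the upper
#' index), totals `s_j = sum_i c_ij u_hat[i,j,]`, outputs `v_j = squash(s_j)`
#' and the agreement update `b_ij <- b_ij + u_hat[i,j,] . v_j`.
#'
#' @param u_hat prediction tensor `[n_in x n_out x d_out]`.
#' @param r number of routing iterations (>= 1).
#' @return `list(v = [n_out x d_out], state = )` where `state` holds the
#'   final `b`, `c`, `s`, `v`.
#' @export
dynamic_routing <- function(u_hat, r = 3) {
  if (r < 1) stop("routing iterations r must be >= 1")
  stopifnot(length(dim(u_hat)) == 3, all(is.finite(u_hat)))
  n_in <- dim(u_hat)[1]; n_out <- dim(u_hat)[2]; d <- dim(u_hat)[3]
  b <- matrix(0, n_in, n_out)
  v <- matrix(0, n_out, d)
  cc <- s <- NULL
  for (it in seq_len(r)) {
    eb <- exp(b - apply(b, 1, max))
    cc <- eb / rowSums(eb)
    s <- matrix(0, n_out, d)
    for (j in seq_len(n_out)) {
      s[j, ] <- colSums(cc[, j] * matrix(u_hat[, j, ], n_in, d))
    }
    v <- squash(s)
    for (j in seq_len(n_out)) {
      b[, j] <- b[, j] + matrix(u_hat[, j, ], n_in, d) %*% v[j, ]
    }
  }
  list(v = v, state = list(b = b, c = cc, s = s, v = v))
}

#' Capsule classification head (pure forward)
#'
#' Reshapes a `[t x channels]` feature map into `t * channels / d_in`
#' primary capsules of width `d_in`, squashes them, forms predictions
#' `u_hat[i,j,] = u_i %*% W[i,j,,]`, routes for `r` iterations, and returns
#' class scores: a softmax over the output-capsule lengths `|v_j|`.
#'
#' @param features numeric matrix `[t x channels]`.
#' @param params list with `W` (`[n_in x n_out x d_in x d_out]` transform
#'   tensor) and `r` routing iterations.
#' @return Numeric vector of `n_out` class scores summing to 1.
#' @export
capsule_head <- function(features, params) {
  stopifnot(is.matrix(features))
  W <- params$W
  r <- params$r %||% 3
  d_in <- dim(W)[3]; d_out <- dim(W)[4]
  n_in <- dim(W)[1]; n_out <- dim(W)[2]
  total <- length(features)
  if (total %% d_in != 0 || total / d_in != n_in) {
    stop("feature map of ", nrow(features), " x ", ncol(features),
         " = ", total, " values cannot form ", n_in,
         " primary capsules of dimension ", d_in)
  }
  # row-major reshape: capsule i takes d_in consecutive values of the
  # flattened (time-major) feature map
  u <- matrix(as.vector(t(features)), n_in, d_in, byrow = TRUE)
  u <- squash(u)
  u_hat <- array(0, c(n_in, n_out, d_out))
  for (i in seq_len(n_in)) {
    for (j in seq_len(n_out)) {
      u_hat[i, j, ] <- u[i, ] %*% W[i, j, , ]
    }
  }
  v <- dynamic_routing(u_hat, r)$v
  lens <- sqrt(rowSums(v^2))
  e <- exp(lens - max(lens))
  e / sum(e)
}

#' Scaled dot-product attention
#'
#' `Attn(Q, K, V) = softmax(Q K^T / sqrt(d_k)) V`, softmax taken row-wise.
#'
#' @param Q,K,V numeric matrices with `d_k = ncol(Q) = ncol(K)` and
#'   `nrow(K) = nrow(V)`.
#' @return Matrix `[nrow(Q) x ncol(V)]`.
#' @export
attention <- function(Q, K, V) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  scores <- tcrossprod(Q, K) / sqrt(ncol(Q))
  w <- exp(scores - apply(scores, 1, max))
  w <- w / rowSums(w)
  w %*% V
}

#' Multi-head self-attention (pure forward)
#'
#' Projects `X` to queries/keys/values, splits the model width into
#' `n_heads` slices, runs scaled dot-product attention per head,
#' concatenates and output-projects.
#'
#' @param X numeric matrix `[t x d_model]`.
#' @param p list with square projection matrices `Wq`, `Wk`, `Wv`, `Wo`
#'   (`d_model x d_model`) and `n_heads` dividing `d_model`.
#' @return Matrix `[t x d_model]`.
#' @export
multi_head_attention <- function(X, p) {
  d <- ncol(X)
  h <- p$n_heads
  if (d %% h != 0) stop("d_model (", d, ") not divisible by n_heads (", h, ")")
  dk <- d %/% h
  Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
  out <- matrix(0, nrow(X), d)
  for (head in seq_len(h)) {
    cols <- ((head - 1) * dk + 1):(head * dk)
    out[, cols] <- attention(Q[, cols, drop = FALSE],
                             K[, cols, drop = FALSE],
                             V[, cols, drop = FALSE])
  }
  out %*% p$Wo
}

# layer normalisation over the feature axis of each row
layer_norm_rows <- function(X, gamma, beta, epsilon = 1e-7) {
  m <- rowMeans(X)
  v <- rowMeans((X - m)^2)
  xhat <- (X - m) / sqrt(v + epsilon)
  sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
}

#' Transformer encoder block (pure forward)
#'
#' `X -> LayerNorm(X + MHA(X)) -> LayerNorm(. + MLP(.))` where the MLP is two
#' affine maps with a SELU between (post-norm residual arrangement).
#'
#' @param X numeric matrix `[t x d_model]`.
#' @param p list with the [multi_head_attention()] parameters plus MLP
#'   weights `W1` (`d_model x d_ff`), `b1`, `W2` (`d_ff x d_model`), `b2`,
#'   and layer-norm parameters `ln1_gamma`, `ln1_beta`, `ln2_gamma`,
#'   `ln2_beta` (default 1/0).
#' @return Matrix `[t x d_model]`.
#' @export
transformer_block <- function(X, p) {
  d <- ncol(X)
  g1 <- p$ln1_gamma %||% rep(1, d); b1 <- p$ln1_beta %||% rep(0, d)
  g2 <- p$ln2_gamma %||% rep(1, d); b2 <- p$ln2_beta %||% rep(0, d)
  a <- layer_norm_rows(X + multi_head_attention(X, p), g1, b1)
  h <- selu(sweep(a %*% p$W1, 2, p$b1, "+"))
  m <- sweep(h %*% p$W2, 2, p$b2, "+")
  layer_norm_rows(a + m, g2, b2)
}
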