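# Mathematical primitives against naive oracles and closed forms.

test_that("SELU matches its defining constants", {
  expect_equal(selu(1), selu_constants$lambda, tolerance = 1e-12)
  expect_equal(round(selu(1), 4), 1.0507)
  expect_equal(selu(0), 0)
  # negative branch saturates at -lambda * alpha
  expect_equal(round(-selu(-40) / selu_constants$lambda, 5), 1.67326)
  # elementwise over a matrix, preserving shape
  m <- matrix(c(-1, 0, 1, 2), 2, 2)
  expect_equal(dim(selu(m)), c(2, 2))
  expect_equal(selu(m)[1, 1],
               selu_constants$lambda * selu_constants$alpha * expm1(-1))
})

test_that("batch_norm follows the normalisation transform", {
  set.seed(1)
  x <- matrix(rnorm(200, mean = 3, sd = 2), 50, 4)
  # batch statistics, identity affine: mean 0, unit variance
  z <- batch_norm(x, list(gamma = 1, beta = 0, epsilon = 1e-12))
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_equal(apply(z, 2, function(v) mean((v - mean(v))^2)), rep(1, 4),
               tolerance = 1e-6)
  # gamma/beta rescale and retranslate
  z2 <- batch_norm(z, list(gamma = 2, beta = 3,
                           mean = rep(0, 4), var = rep(1, 4),
                           epsilon = 0))
  expect_equal(colMeans(z2), rep(3, 4), tolerance = 1e-8)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  expect_equal(apply(z2, 2, pop_sd), rep(2, 4), tolerance = 1e-6)
  # constant feature collapses to beta
  const <- matrix(5, 10, 1)
  expect_equal(batch_norm(const, list(gamma = 1.5, beta = -2,
                                      epsilon = 1e-3))[, 1],
               rep(-2, 10))
})

test_that("squash compresses norms into [0, 1) and keeps direction", {
  expect_equal(squash(c(0, 0)), c(0, 0))
  expect_equal(squash(c(1, 0)), c(0.5, 0), tolerance = 1e-9)
  set.seed(2)
  for (scale in c(0.1, 1, 10, 1e4)) {
    s <- rnorm(5) * scale
    v <- squash(s)
    expect_lt(sqrt(sum(v^2)), 1)
    # direction preserved
    expect_equal(v / sqrt(sum(v^2)), s / sqrt(sum(s^2)), tolerance = 1e-6)
  }
  # norm is monotone in |s| and approaches 1
  norms <- sapply(c(0.5, 1, 2, 8, 50), function(k)
    sqrt(sum(squash(c(k, 0))^2)))
  expect_true(all(diff(norms) > 0))
  expect_gt(norms[length(norms)], 0.999)
})

test_that("dynamic routing equals the closed form at r = 1", {
  set.seed(3)
  u_hat <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  out <- dynamic_routing(u_hat, 1)
  for (j in 1:3) {
    expect_equal(out$v[j, ], squash(colSums(u_hat[, j, ]) / 3),
                 tolerance = 1e-12)
  }
  expect_error(dynamic_routing(u_hat, 0), ">= 1")
})

test_that("single-capsule routing repeatedly squashes its input", {
  u_hat <- array(c(2, 0), c(1, 1, 2))
  out <- dynamic_routing(u_hat, 3)
  # softmax over one output capsule is 1, so v = squash(u) at every pass
  expect_equal(out$v[1, ], squash(c(2, 0)), tolerance = 1e-12)
  expect_equal(out$v[1, ], c(0.8, 0), tolerance = 1e-9)
})

test_that("routing matches the naive triple-loop oracle", {
  set.seed(4)
  for (case in 1:60) {
    n_in <- sample(1:4, 1); n_out <- sample(1:3, 1)
    d <- sample(1:4, 1); r <- sample(1:3, 1)
    u_hat <- array(rnorm(n_in * n_out * d, sd = 2), c(n_in, n_out, d))
    got <- dynamic_routing(u_hat, r)
    ref <- naive_routing(u_hat, r)
    expect_equal(got$v, ref$v, tolerance = 1e-10)
    expect_equal(got$state$b, ref$b, tolerance = 1e-10)
    expect_equal(got$state$c, ref$c, tolerance = 1e-10)
    expect_equal(rowSums(got$state$c), rep(1, n_in), tolerance = 1e-10)
  }
})

test_that("coupling mass concentrates on the agreeing capsule", {
  # all lower capsules predict the same large vector for j = 1 and noise
  # for j = 2: c[, 1] should grow monotonically over iterations
  set.seed(5)
  n_in <- 4; d <- 3
  u_hat <- array(rnorm(n_in * 2 * d, sd = 0.01), c(n_in, 2, d))
  for (i in 1:n_in) u_hat[i, 1, ] <- c(5, 0, 0)
  c1 <- sapply(1:3, function(r) mean(dynamic_routing(u_hat, r)$state$c[, 1]))
  expect_true(all(diff(c1) > 0))
  expect_gt(c1[3], 0.5)
})

test_that("capsule_head reshapes, routes and normalises", {
  # 2 x 512 feature map with d_in = 16 -> 64 primary capsules
  W <- array(0, c(64, 2, 16, 16))
  scores <- capsule_head(matrix(0.1, 2, 512), list(W = W, r = 3))
  expect_equal(length(scores), 2)
  # zero transform -> zero lengths -> uniform scores
  expect_equal(scores, c(0.5, 0.5))

  set.seed(6)
  W2 <- array(rnorm(64 * 2 * 16 * 16, sd = 0.1), c(64, 2, 16, 16))
  s2 <- capsule_head(matrix(rnorm(1024), 2, 512), list(W = W2, r = 3))
  expect_equal(sum(s2), 1, tolerance = 1e-12)
  expect_true(all(s2 > 0 & s2 < 1))

  expect_error(capsule_head(matrix(1, 2, 511), list(W = W2, r = 3)),
               "cannot form")
})

test_that("attention matches the naive loop oracle", {
  set.seed(7)
  for (case in 1:25) {
    n <- sample(1:5, 1); dk <- sample(1:6, 1)
    Q <- matrix(rnorm(n * dk), n, dk)
    K <- matrix(rnorm(n * dk), n, dk)
    V <- matrix(rnorm(n * dk), n, dk)
    expect_equal(attention(Q, K, V), naive_attention(Q, K, V),
                 tolerance = 1e-12)
  }
  # single token: softmax over one element is 1, output = V
  Q1 <- matrix(rnorm(3), 1); K1 <- matrix(rnorm(3), 1)
  V1 <- matrix(rnorm(3), 1)
  expect_equal(attention(Q1, K1, V1), V1, tolerance = 1e-14)
  # zero scores: uniform weights, output = column means of V
  Z <- matrix(0, 4, 3)
  V4 <- matrix(rnorm(12), 4, 3)
  out <- attention(Z, Z, V4)
  for (i in 1:4) expect_equal(out[i, ], colMeans(V4), tolerance = 1e-12)
})

test_that("multi-head attention reduces to attention for one head", {
  set.seed(8)
  d <- 6; t <- 4
  X <- matrix(rnorm(t * d), t, d)
  p <- list(Wq = diag(d), Wk = diag(d), Wv = diag(d), Wo = diag(d),
            n_heads = 1)
  expect_equal(multi_head_attention(X, p), attention(X, X, X),
               tolerance = 1e-12)
  expect_error(multi_head_attention(X, list(Wq = diag(d), Wk = diag(d),
                                            Wv = diag(d), Wo = diag(d),
                                            n_heads = 4)),
               "not divisible")
})

test_that("multi-head attention is permutation-equivariant", {
  set.seed(9)
  d <- 8; t <- 5
  X <- matrix(rnorm(t * d), t, d)
  p <- list(Wq = matrix(rnorm(d * d), d), Wk = matrix(rnorm(d * d), d),
            Wv = matrix(rnorm(d * d), d), Wo = matrix(rnorm(d * d), d),
            n_heads = 2)
  perm <- sample(t)
  expect_equal(multi_head_attention(X[perm, ], p),
               multi_head_attention(X, p)[perm, ], tolerance = 1e-10)
})

test_that("transformer block preserves shape and degrades gracefully", {
  set.seed(10)
  d <- 6; t <- 3
  X <- matrix(rnorm(t * d), t, d)
  zero <- matrix(0, d, d)
  p0 <- list(Wq = zero, Wk = zero, Wv = zero, Wo = zero, n_heads = 2,
             W1 = matrix(0, d, 4 * d), b1 = rep(0, 4 * d),
             W2 = matrix(0, 4 * d, d), b2 = rep(0, d))
  # zero MHA/MLP weights: output = LayerNorm(LayerNorm(X))
  ln <- function(m) t(apply(m, 1, function(r)
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-7)))
  expect_equal(transformer_block(X, p0), ln(ln(X)), tolerance = 1e-10)

  p <- list(Wq = matrix(rnorm(d * d), d), Wk = matrix(rnorm(d * d), d),
            Wv = matrix(rnorm(d * d), d), Wo = matrix(rnorm(d * d), d),
            n_heads = 2,
            W1 = matrix(rnorm(d * 4 * d, sd = 0.5), d, 4 * d),
            b1 = rnorm(4 * d),
            W2 = matrix(rnorm(4 * d * d, sd = 0.5), 4 * d, d),
            b2 = rnorm(d))
  expect_equal(dim(transformer_block(X, p)), c(t, d))
})

test_that("transformer block stays finite under random stress inputs", {
  set.seed(11)
  d <- 4
  p <- list(Wq = matrix(rnorm(16), 4), Wk = matrix(rnorm(16), 4),
            Wv = matrix(rnorm(16), 4), Wo = matrix(rnorm(16), 4),
            n_heads = 2,
            W1 = matrix(rnorm(16 * 4), 4, 16), b1 = rnorm(16),
            W2 = matrix(rnorm(16 * 4), 16, 4), b2 = rnorm(4))
  for (i in 1:1000) {
    X <- matrix(rnorm(8, sd = sample(c(0.01, 1, 100), 1)), 2, 4)
    expect_true(all(is.finite(transformer_block(X, p))))
  }
})
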