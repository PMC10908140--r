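# The training engine: hand-derived gradients vs finite differences,
# batched layers vs the pure single-sample primitives, determinism.

fd_layer_check <- function(layer, X, n_input = 25, n_param = 15,
                           training = FALSE, eps = 1e-6) {
  rngd <- eegcaps:::rng_stream(1, "fd")
  fwd <- function(l, x) eegcaps:::layer_forward(l, x, training, rngd)$out
  fw <- eegcaps:::layer_forward(layer, X, training, rngd)
  R <- array(rnorm(length(fw$out)), dim(fw$out) %||% length(fw$out))
  bw <- eegcaps:::layer_backward(layer, fw$cache, R)
  errs <- c()
  idx <- sample(length(X), min(n_input, length(X)))
  for (i in idx) {
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    g <- sum((fwd(layer, Xp) - fwd(layer, Xm)) * R) / (2 * eps)
    errs <- c(errs, abs(g - bw$dx[i]))
  }
  for (pn in names(layer$params)) {
    P <- layer$params[[pn]]
    for (i in sample(length(P), min(n_param, length(P)))) {
      lp <- layer; lp$params[[pn]][i] <- P[i] + eps
      lm <- layer; lm$params[[pn]][i] <- P[i] - eps
      g <- sum((fwd(lp, X) - fwd(lm, X)) * R) / (2 * eps)
      errs <- c(errs, abs(g - bw$grads[[pn]][i]))
    }
  }
  max(errs)
}

test_that("layer gradients match finite differences", {
  set.seed(31)
  rng <- eegcaps:::rng_stream(7, "init")
  X3 <- array(rnorm(4 * 10 * 3), c(4, 10, 3))
  expect_lt(fd_layer_check(eegcaps:::layer_conv1d(rng, "c", 3, 5), X3), 1e-6)
  expect_lt(fd_layer_check(eegcaps:::layer_conv1d(rng, "c1", 1, 4),
                           array(rnorm(3 * 8), c(3, 8, 1))), 1e-6)
  expect_lt(fd_layer_check(eegcaps:::layer_maxpool("p"), X3), 1e-6)
  expect_lt(fd_layer_check(eegcaps:::layer_selu("s"), X3), 1e-6)
  expect_lt(fd_layer_check(eegcaps:::layer_gmaxpool("g"), X3), 1e-6)
  expect_lt(fd_layer_check(eegcaps:::layer_tmeanpool("t"), X3), 1e-6)
  expect_lt(fd_layer_check(eegcaps:::layer_dense(rng, "d", 8, 4),
                           matrix(rnorm(48), 6, 8)), 1e-6)
  expect_lt(fd_layer_check(eegcaps:::layer_tfblock(rng, "tf", 8, 2),
                           array(rnorm(3 * 2 * 8), c(3, 2, 8))), 1e-5)
  # batch norm uses batch statistics: check in training mode
  bn <- eegcaps:::layer_batchnorm("bn", 3)
  bn$params$gamma <- runif(3, 0.5, 1.5)
  bn$params$beta <- rnorm(3)
  expect_lt(fd_layer_check(bn, X3, training = TRUE), 1e-6)
  # capsule gradients are exact at r = 1 (couplings are constants there)
  caps <- eegcaps:::layer_capsule(rng, "cap", t = 2, c = 8, n_out = 3,
                                  d_in = 4, d_out = 4, r = 1)
  expect_lt(fd_layer_check(caps, array(rnorm(5 * 2 * 8), c(5, 2, 8))), 1e-6)
})

test_that("batched capsule layer agrees with the pure capsule_head", {
  set.seed(32)
  rng <- eegcaps:::rng_stream(3, "init")
  caps <- eegcaps:::layer_capsule(rng, "cap", t = 2, c = 12, n_out = 4,
                                  d_in = 6, d_out = 5, r = 3)
  X <- array(rnorm(7 * 2 * 12), c(7, 2, 12))
  lens <- eegcaps:::layer_forward(caps, X)$out
  for (b in 1:7) {
    scores <- capsule_head(matrix(X[b, , ], 2, 12),
                           list(W = caps$params$W, r = 3))
    e <- exp(lens[b, ] - max(lens[b, ]))
    expect_equal(e / sum(e), scores, tolerance = 1e-10)
  }
})

test_that("batched transformer block agrees with the pure primitive", {
  set.seed(33)
  rng <- eegcaps:::rng_stream(5, "init")
  tf <- eegcaps:::layer_tfblock(rng, "tf", d_model = 8, n_heads = 2)
  # pure-function parameter list (no projection biases there: zero them)
  for (bn in c("bq", "bk", "bv", "bo")) tf$params[[bn]] <- rep(0, 8)
  X <- array(rnorm(4 * 3 * 8), c(4, 3, 8))
  out <- eegcaps:::layer_forward(tf, X)$out
  p <- tf$params
  p$n_heads <- 2
  for (b in 1:4) {
    pure <- transformer_block(matrix(X[b, , ], 3, 8), p)
    expect_equal(matrix(out[b, , ], 3, 8), pure, tolerance = 1e-10)
  }
})

test_that("extractor output width is 512-plan wide and t follows pooling
           arithmetic", {
  expected_t <- function(len, blocks = 6) {
    for (b in seq_len(blocks)) if (len >= 2) len <- len %/% 2
    len
  }
  for (len in c(8, 13, 40, 64, 100, 178, 512)) {
    spec <- architecture_spec("cnn_fully", input_len = len, width_scale = 32)
    ext <- suppressMessages(build_feature_extractor(spec))
    expect_equal(ext$out_t, expected_t(len))
    X <- array(rnorm(2 * len), c(2, len, 1))
    out <- X
    rngd <- eegcaps:::rng_stream(1, "t")
    for (l in ext$layers) out <- eegcaps:::layer_forward(l, out)$out
    expect_equal(dim(out), c(2, expected_t(len), ext$out_channels))
  }
  # unscaled plan ends at 512 channels
  ext <- build_feature_extractor(architecture_spec("cnn_fully"))
  expect_equal(ext$out_channels, 512)
})

test_that("zero input with zero biases stays zero through the extractor", {
  spec <- architecture_spec("cnn_fully", input_len = 32, width_scale = 32,
                            dropout = 0)
  ext <- build_feature_extractor(spec)
  out <- array(0, c(2, 32, 1))
  for (l in ext$layers) {
    if (l$type == "batchnorm") next  # batch stats of zeros stay zero anyway
    out <- eegcaps:::layer_forward(l, out)$out
  }
  expect_true(all(out == 0))
})

test_that("forward passes are reproducible with dropout disabled", {
  spec <- architecture_spec("cnn_caps", input_len = 40, n_classes = 2,
                            width_scale = 16, dropout = 0, seed = 4)
  m <- suppressMessages(build_model(spec))
  x <- matrix(rnorm(3 * 40), 3, 40)
  p1 <- predict(m, x)
  p2 <- predict(m, x)
  expect_identical(p1, p2)
})

test_that("identical seeds give identical models and training traces", {
  s <- to_binary(synth_generate(synth_config(n_per_class = 10, seed = 5)))
  spec <- architecture_spec("cnn_fully", input_len = 178, n_classes = 2,
                            width_scale = 32, epochs = 2, batch_size = 16,
                            seed = 9)
  m1 <- train_model(build_model(spec), s)
  m2 <- train_model(build_model(spec), s)
  expect_equal(m1$history, m2$history, tolerance = 1e-12)
  expect_equal(m1$layers[[1]]$params$W, m2$layers[[1]]$params$W,
               tolerance = 1e-12)
})

test_that("zero epochs leave the model untouched", {
  spec <- architecture_spec("cnn_fully", input_len = 20, n_classes = 2,
                            width_scale = 32, seed = 2)
  m <- suppressMessages(build_model(spec))
  s <- segment_set(matrix(rnorm(80), 4, 20), c(0L, 1L, 0L, 1L),
                   label_scheme = "binary")
  m0 <- train_model(m, s, epochs = 0)
  expect_equal(m0$layers[[1]]$params$W, m$layers[[1]]$params$W)
  expect_equal(nrow(m0$history), 0)
})
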