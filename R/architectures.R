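#' Declarative description of a model variant
#'
#' Captures the conv backbone plan and head hyperparameters of the five
#' model variants:
#' \describe{
#'   \item{cnn_fully}{conv backbone -> global max pool -> dense stack.}
#'   \item{cnn_caps}{conv backbone -> capsule head with dynamic routing.}
#'   \item{cnn_tf}{conv backbone -> transformer encoder blocks -> time-mean
#'     pool -> softmax layer (heads = 16, layers = 2 by default).}
#'   \item{cnn_tf_fully}{backbone -> transformer (heads 16, layers 1) ->
#'     dense stack.}
#'   \item{cnn_tf_caps}{backbone -> transformer (heads 8, layers 1) ->
#'     capsule head.}
#' }
#' The backbone is six blocks of same-padded kernel-3 convolutions
#' (2x32, 2x64, 3x128, 3x256, 3x512, 3x512 channels), each block closed by
#' max-pool (size 2, stride 2, floor) and dropout 0.5; a 178-sample input
#' yields a (2, 512) feature map, a 40-sample (PCA) input yields (1, 512)
#' because a pool that would shrink the map below length 1 is skipped.
#' Training defaults: Adam (lr 0.001), 500 epochs, batch 128.
#'
#' `width_scale` divides every conv channel width and dense-head width
#' (minimum 2) for desk-scale experiments; `width_scale = 8` is the scaled
#' study size used throughout the package's tests.
#'
#' @param variant one of `"cnn_fully"`, `"cnn_caps"`, `"cnn_tf"`,
#'   `"cnn_tf_fully"`, `"cnn_tf_caps"`.
#' @param input_len input segment length (178, or 40 after PCA).
#' @param n_classes 2 or 5.
#' @param conv_plan list of `c(block_size, channels)` pairs.
#' @param kernel convolution kernel size.
#' @param dropout dropout rate in [0, 1).
#' @param dense_widths dense-head stack widths.
#' @param n_heads,n_layers transformer head count / block count (defaults
#'   per variant).
#' @param num_caps capsule width (both primary and output capsule
#'   dimension).
#' @param routing_iters routing iterations r.
#' @param mlp_ratio transformer MLP hidden width as a multiple of d_model.
#' @param lr,epochs,batch_size Adam learning rate, epochs, batch size.
#' @param width_scale divisor applied to conv channels and dense widths.
#' @param use_margin_loss use the capsule margin loss instead of softmax
#'   cross-entropy (capsule variants only).
#' @param positional_encoding add sinusoidal positional encoding before the
#'   transformer blocks (off by default; the feature map has at most two
#'   positions).
#' @param seed integer seed for weight initialisation and batching.
#' @return A list of class `architecture_spec`.
#' @export
architecture_spec <- function(variant = c("cnn_fully", "cnn_caps", "cnn_tf",
                                          "cnn_tf_fully", "cnn_tf_caps"),
                              input_len = 178, n_classes = 2,
                              conv_plan = list(c(2, 32), c(2, 64), c(3, 128),
                                               c(3, 256), c(3, 512),
                                               c(3, 512)),
                              kernel = 3, dropout = 0.5,
                              dense_widths = c(1024, 512, 256, 128, 128, 64,
                                               32, 16),
                              n_heads = NULL, n_layers = NULL, num_caps = 16,
                              routing_iters = 3, mlp_ratio = 4,
                              lr = 0.001, epochs = 500, batch_size = 128,
                              width_scale = 1, use_margin_loss = FALSE,
                              positional_encoding = FALSE, seed = 1L) {
  variant <- match.arg(variant)
  defaults <- switch(variant,
    cnn_tf = list(n_heads = 16, n_layers = 2),
    cnn_tf_fully = list(n_heads = 16, n_layers = 1),
    cnn_tf_caps = list(n_heads = 8, n_layers = 1),
    list(n_heads = NA, n_layers = NA))
  n_heads <- n_heads %||% defaults$n_heads
  n_layers <- n_layers %||% defaults$n_layers
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  chans <- vapply(conv_plan, `[`, 0, 2)
  if (is.unsorted(chans)) {
    stop("conv_plan channel widths must be non-decreasing")
  }
  if (width_scale != 1) {
    conv_plan <- lapply(conv_plan, function(b)
      c(b[1], max(2, b[2] %/% width_scale)))
    dense_widths <- pmax(2, dense_widths %/% width_scale)
  }
  structure(list(variant = variant, input_len = input_len,
                 n_classes = n_classes, conv_plan = conv_plan,
                 kernel = kernel, dropout = dropout,
                 dense_widths = dense_widths, n_heads = n_heads,
                 n_layers = n_layers, num_caps = num_caps,
                 routing_iters = routing_iters, mlp_ratio = mlp_ratio,
                 lr = lr, epochs = epochs, batch_size = batch_size,
                 width_scale = width_scale,
                 use_margin_loss = use_margin_loss,
                 positional_encoding = positional_encoding,
                 seed = as.integer(seed)),
            class = "architecture_spec")
}

#' Build the convolutional feature extractor
#'
#' Six blocks of same-padded kernel-3 convolutions with batch normalisation
#' and SELU, each block closed by max-pool (size 2, stride 2, floor) and
#' dropout. A pool that would reduce the map length below 1 is skipped (with
#' a message), which is what keeps short PCA inputs viable.
#'
#' @param spec an [architecture_spec()].
#' @param rng internal RNG stream (derived from `spec$seed` when NULL).
#' @return A list with `layers`, `out_t` (final map length) and
#'   `out_channels` (always the last plan width).
#' @export
build_feature_extractor <- function(spec, rng = NULL) {
  stopifnot(inherits(spec, "architecture_spec"))
  rng <- rng %||% rng_stream(spec$seed, "init_extractor")
  layers <- list()
  len <- spec$input_len
  c_in <- 1L
  for (bi in seq_along(spec$conv_plan)) {
    block <- spec$conv_plan[[bi]]
    for (l in seq_len(block[1])) {
      nm <- paste0("conv", bi, "_", l)
      layers <- c(layers, list(
        layer_conv1d(rng, nm, c_in, block[2], spec$kernel),
        layer_batchnorm(paste0("bn", bi, "_", l), block[2]),
        layer_selu(paste0("selu", bi, "_", l))))
      c_in <- block[2]
    }
    if (len >= 2) {
      layers <- c(layers, list(layer_maxpool(paste0("pool", bi))))
      len <- len %/% 2L
    } else {
      message("block ", bi, ": pool skipped (map length ", len,
              " cannot be halved)")
    }
    layers <- c(layers, list(layer_dropout(paste0("drop", bi),
                                           spec$dropout)))
  }
  list(layers = layers, out_t = len, out_channels = c_in)
}

#' Build the dense classification head
#'
#' Global max pool over time, then the dense stack (each width followed by
#' batch normalisation and SELU), then the output layer (softmax applied in
#' the loss / prediction).
#'
#' @param spec an [architecture_spec()].
#' @param d_in input width (extractor channel count).
#' @param rng internal RNG stream.
#' @return A list of layers mapping `[n, t, d_in]` to `[n, n_classes]`
#'   logits.
#' @export
build_dense_head <- function(spec, d_in = 512, rng = NULL) {
  rng <- rng %||% rng_stream(spec$seed, "init_dense")
  layers <- list(layer_gmaxpool("gmax"))
  cur <- d_in
  for (wi in seq_along(spec$dense_widths)) {
    w <- spec$dense_widths[wi]
    layers <- c(layers, list(
      layer_dense(rng, paste0("fc", wi), cur, w),
      layer_batchnorm(paste0("fc_bn", wi), w),
      layer_selu(paste0("fc_selu", wi))))
    cur <- w
  }
  c(layers, list(layer_dense(rng, "fc_out", cur, spec$n_classes)))
}

# sinusoidal positional encoding [t x d]
positional_encoding_matrix <- function(t, d) {
  pe <- matrix(0, t, d)
  pos <- seq_len(t) - 1
  for (k in seq_len(d)) {
    i <- (k - 1) %/% 2
    angle <- pos / 10000^(2 * i / d)
    pe[, k] <- if (k %% 2 == 1) sin(angle) else cos(angle)
  }
  pe
}

#' Assemble a trainable model variant
#'
#' @param spec an [architecture_spec()].
#' @return An object of class `eegcaps_model` holding the layer list, the
#'   Adam state, and the spec.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  rng <- rng_stream(spec$seed, "init_model")
  ext <- build_feature_extractor(spec, rng)
  layers <- ext$layers
  d_model <- ext$out_channels
  t_out <- ext$out_t

  needs_tf <- spec$variant %in% c("cnn_tf", "cnn_tf_fully", "cnn_tf_caps")
  if (needs_tf) {
    for (li in seq_len(spec$n_layers)) {
      layers <- c(layers, list(
        layer_tfblock(rng, paste0("tf", li), d_model, spec$n_heads,
                      spec$mlp_ratio)))
    }
  }
  head_layers <- switch(spec$variant,
    cnn_fully = ,
    cnn_tf_fully = build_dense_head(spec, d_model, rng),
    cnn_caps = ,
    cnn_tf_caps = list(layer_capsule(rng, "caps", t_out, d_model,
                                     spec$n_classes,
                                     d_in = spec$num_caps,
                                     d_out = spec$num_caps,
                                     r = spec$routing_iters)),
    cnn_tf = list(layer_tmeanpool("tmean"),
                  layer_dense(rng, "fc_out", d_model, spec$n_classes)))
  layers <- c(layers, head_layers)

  model <- structure(
    list(layers = layers, spec = spec, out_t = t_out, d_model = d_model,
         opt = NULL, class_levels = NULL, history = NULL,
         pos_enc = if (needs_tf && spec$positional_encoding) {
           positional_encoding_matrix(t_out, d_model)
         } else NULL),
    class = "eegcaps_model")
  model$opt <- adam_init(model$layers)
  model
}

#' @export
print.eegcaps_model <- function(x, ...) {
  cat("<eegcaps_model> variant:", x$spec$variant,
      "| input_len:", x$spec$input_len,
      "| classes:", x$spec$n_classes, "\n")
  cat("  feature map: (", x$out_t, ",", x$d_model, ") |",
      length(x$layers), "layers\n")
  if (!is.null(x$history)) {
    h <- x$history
    cat("  trained", nrow(h), "epochs; final loss",
        formatC(h$loss[nrow(h)], digits = 4, format = "f"),
        "acc", formatC(h$accuracy[nrow(h)], digits = 3, format = "f"), "\n")
  }
  invisible(x)
}

# Forward through all layers. Returns logits and (optionally) all caches.
model_forward <- function(model, X, training = FALSE, rng = NULL,
                          keep_caches = FALSE, keep_outputs = FALSE) {
  tf_seen <- FALSE
  caches <- if (keep_caches) vector("list", length(model$layers)) else NULL
  outputs <- if (keep_outputs) vector("list", length(model$layers)) else NULL
  updates <- list()
  out <- X
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    if (!is.null(model$pos_enc) && layer$type == "tfblock" && !tf_seen) {
      n <- dim(out)[1]
      for (p in seq_len(dim(out)[2])) {
        out[, p, ] <- out[, p, ] +
          matrix(model$pos_enc[p, ], n, dim(out)[3], byrow = TRUE)
      }
      tf_seen <- TRUE
    }
    fw <- layer_forward(layer, out, training = training, rng = rng)
    out <- fw$out
    if (keep_caches) caches[[li]] <- fw$cache
    if (keep_outputs) outputs[[li]] <- out
    if (!is.null(fw$state_update)) updates[[as.character(li)]] <- fw$state_update
  }
  list(logits = out, caches = caches, outputs = outputs,
       state_updates = updates)
}

# Backward from dlogits; returns per-layer grads and optionally dx at a layer
model_backward <- function(model, caches, dlogits, stop_at = 0L) {
  grads <- vector("list", length(model$layers))
  dout <- dlogits
  for (li in rev(seq_along(model$layers))) {
    bw <- layer_backward(model$layers[[li]], caches[[li]], dout)
    grads[[li]] <- bw$grads
    dout <- bw$dx
    if (li == stop_at + 1L) break
  }
  list(grads = grads, dx = dout)
}

signals_to_input <- function(signals) {
  array(signals, c(nrow(signals), ncol(signals), 1L))
}

# Re-estimate batch-norm statistics under the inference distribution.
#
# Training collects BN moments with dropout active; at inference dropout is
# off, so activations reaching deeper BN layers have smaller variance than
# the moments predict ("variance shift"). With wide layers and long
# schedules the mismatch is mild, but at desk scale it compounds across the
# stacked BN layers. After the optimisation loop we therefore freeze the
# weights, stream the training data once with dropout disabled, and replace
# every BN layer's running moments by the batch moments observed layer by
# layer (each layer sees inputs normalised with its predecessors' already
# recalibrated statistics).
bn_recalibrate <- function(model, X, max_rows = 1024) {
  n <- dim(X)[1]
  if (n > max_rows) {  # evenly spaced, deterministic calibration subsample
    X <- X[round(seq(1, n, length.out = max_rows)), , , drop = FALSE]
  }
  acts <- X  # calibration sample flows through once, layer by layer
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    if (layer$type == "batchnorm") {
      dims <- dim(acts)
      Xm <- if (length(dims) == 3) {
        matrix(acts, dims[1] * dims[2], dims[3])
      } else acts
      mu <- colMeans(Xm)
      model$layers[[li]]$config$running_mean <- mu
      model$layers[[li]]$config$running_var <-
        colMeans(sweep(Xm, 2, mu)^2)
    }
    # dropout is inactive (training = FALSE); BN layers use the moments
    # just assigned, so each layer is calibrated on its true inference input
    acts <- layer_forward(model$layers[[li]], acts,
                          training = FALSE)$out
  }
  model
}

# map raw labels to 1..K indices using stored class levels
encode_labels <- function(model, labels) {
  idx <- match(labels, model$class_levels)
  if (anyNA(idx)) {
    stop("labels ", paste(unique(labels[is.na(idx)]), collapse = ", "),
         " not in model classes (", paste(model$class_levels, collapse = ", "),
         ")")
  }
  idx
}

apply_state_updates <- function(model, updates) {
  for (li_chr in names(updates)) {
    li <- as.integer(li_chr)
    model$layers[[li]]$config$running_mean <- updates[[li_chr]]$running_mean
    model$layers[[li]]$config$running_var <- updates[[li_chr]]$running_var
  }
  model
}

#' Train a model with Adam on cross-entropy
#'
#' Mini-batch training at the configured batch size and learning rate.
#' Capsule variants can instead minimise the margin loss when the spec sets
#' `use_margin_loss`. Training is deterministic under a fixed spec seed.
#' Aborts with a diagnostic if the loss becomes non-finite.
#'
#' After the optimisation loop the batch-normalisation running statistics
#' are re-estimated in a single pass over the training data with dropout
#' disabled, so inference-mode normalisation matches the distribution the
#' network actually sees at prediction time (dropout before a normalisation
#' layer otherwise shifts the variance its running moments were collected
#' under).
#'
#' @param model an [build_model()] output.
#' @param train a [segment_set()] whose label scheme matches
#'   `spec$n_classes`.
#' @param epochs,batch_size,lr optional overrides of the spec values.
#' @param verbose print per-epoch loss/accuracy.
#' @return The trained model; `model$history` is a data frame with per-epoch
#'   `loss` and `accuracy`.
#' @export
train_model <- function(model, train, epochs = NULL, batch_size = NULL,
                        lr = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "eegcaps_model"), inherits(train, "segment_set"))
  spec <- model$spec
  epochs <- epochs %||% spec$epochs
  batch_size <- batch_size %||% spec$batch_size
  lr <- lr %||% spec$lr
  levels_ <- sort(unique(train$labels))
  if (length(levels_) > spec$n_classes) {
    stop("training labels have ", length(levels_), " classes; model expects ",
         spec$n_classes)
  }
  if (is.null(model$class_levels)) {
    model$class_levels <- if (train$label_scheme == "binary") c(0L, 1L) else 1:5
    model$class_levels <- model$class_levels[seq_len(spec$n_classes)]
    if (!all(levels_ %in% model$class_levels)) model$class_levels <- levels_
  }
  if (epochs == 0) {
    model$history <- model$history %||%
      data.frame(loss = numeric(0), accuracy = numeric(0))
    return(model)
  }
  y <- encode_labels(model, train$labels)
  X <- signals_to_input(train$signals)
  n <- dim(X)[1]
  rng_batch <- rng_stream(spec$seed, "train_batches")
  rng_drop <- rng_stream(spec$seed, "train_dropout")
  use_margin <- isTRUE(spec$use_margin_loss) &&
    spec$variant %in% c("cnn_caps", "cnn_tf_caps")
  hist_loss <- hist_acc <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    ord <- rng_shuffle(rng_batch, seq_len(n))
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Xb <- X[idx, , , drop = FALSE]
      yb <- y[idx]
      fw <- model_forward(model, Xb, training = TRUE, rng = rng_drop,
                          keep_caches = TRUE)
      model <- apply_state_updates(model, fw$state_updates)
      loss_fn <- if (use_margin) margin_loss else softmax_ce
      ls <- loss_fn(fw$logits, yb)
      if (!is.finite(ls$loss)) {
        stop("non-finite loss at epoch ", ep, " (batch starting ", start,
             "); lower the learning rate or check the input scaling")
      }
      bw <- model_backward(model, fw$caches, ls$dlogits)
      stepped <- adam_step(model$layers, bw$grads, model$opt, lr = lr)
      model$layers <- stepped$layers
      model$opt <- stepped$opt
      ep_loss <- ep_loss + ls$loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(ls$probs, ties.method = "first") == yb)
    }
    hist_loss[ep] <- ep_loss / n
    hist_acc[ep] <- ep_correct / n
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f  acc %.3f\n", ep, hist_loss[ep],
                  hist_acc[ep]))
    }
  }
  model <- bn_recalibrate(model, X)
  new_hist <- data.frame(loss = hist_loss, accuracy = hist_acc)
  model$history <- rbind(model$history, new_hist)
  model
}

#' Predict class probabilities for a segment set
#'
#' @param object a trained `eegcaps_model`.
#' @param s a [segment_set()] (or a signal matrix).
#' @param type `"prob"` for the softmax matrix, `"class"` for hard labels on
#'   the original label scale.
#' @param ... ignored.
#' @return A matrix of probabilities or a vector of labels.
#' @export
predict.eegcaps_model <- function(object, s, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  signals <- if (inherits(s, "segment_set")) s$signals else as.matrix(s)
  fw <- model_forward(object, signals_to_input(signals), training = FALSE)
  probs <- softmax_rows(fw$logits)
  if (type == "prob") return(probs)
  levels_ <- object$class_levels %||% seq_len(ncol(probs))
  levels_[max.col(probs, ties.method = "first")]
}

#' Evaluate a trained model on a test set
#'
#' @param model a trained `eegcaps_model`.
#' @param test a [segment_set()].
#' @return A `fit_report` (see [metrics()]) with the test confusion matrix.
#' @export
evaluate_model <- function(model, test) {
  pred <- predict(model, test, type = "class")
  cm <- confusion(pred, test$labels,
                  classes = model$class_levels %||% sort(unique(test$labels)))
  metrics(cm)
}

#' Grid-iterate transformer head/layer hyperparameters
#'
#' Trains and evaluates a transformer variant for every (heads, layers)
#' combination and reports a comparison table.
#'
#' @param heads vector of attention-head counts.
#' @param layers_grid vector of encoder block counts.
#' @param train,test segment sets.
#' @param variant transformer variant to iterate.
#' @param sort_desc sort rows by accuracy, descending.
#' @param ... further arguments to [architecture_spec()] (e.g.
#'   `width_scale`, `epochs`).
#' @return A data frame with columns `variant`, `num_heads`, `num_layers`,
#'   `accuracy`.
#' @export
iterate_transformer_hparams <- function(heads = c(1, 2, 4, 8, 16),
                                        layers_grid = c(1, 2, 4, 8, 16),
                                        train, test,
                                        variant = "cnn_tf",
                                        sort_desc = FALSE, ...) {
  if (!length(heads) || !length(layers_grid)) stop("grids must be non-empty")
  rows <- list()
  n_classes <- if (train$label_scheme == "binary") 2L else 5L
  for (h in heads) {
    for (l in layers_grid) {
      spec <- architecture_spec(variant = variant,
                                input_len = segment_length(train),
                                n_classes = n_classes,
                                n_heads = h, n_layers = l, ...)
      model <- train_model(build_model(spec), train)
      rep_ <- evaluate_model(model, test)
      rows[[length(rows) + 1]] <- data.frame(
        variant = variant, num_heads = h, num_layers = l,
        accuracy = rep_$accuracy)
    }
  }
  out <- do.call(rbind, rows)
  if (sort_desc) out <- out[order(-out$accuracy), , drop = FALSE]
  rownames(out) <- NULL
  out
}
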