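#' Confusion matrix (predicted rows x actual columns)
#'
#' Tallies predictions against ground truth. Note the orientation: rows are
#' the predicted classes and columns the actual classes (the convention used
#' throughout this package's reports; the transpose of the more common
#' actual-rows layout). The serialised form labels both axes explicitly.
#'
#' @param pred predicted labels.
#' @param actual true labels.
#' @param classes optional class values fixing the matrix order; defaults to
#'   the sorted union of both vectors.
#' @return An object of class `confusion_matrix`: integer matrix `counts`
#'   plus `classes`.
#' @export
confusion <- function(pred, actual, classes = NULL) {
  if (length(pred) != length(actual)) {
    stop("length mismatch: ", length(pred), " predictions vs ",
         length(actual), " actuals")
  }
  classes <- classes %||% sort(unique(c(pred, actual)))
  if (length(pred) && !all(c(pred, actual) %in% classes)) {
    stop("labels outside the class set")
  }
  counts <- table(factor(pred, levels = classes),
                  factor(actual, levels = classes))
  counts <- matrix(as.integer(counts), length(classes), length(classes),
                   dimnames = list(predicted = as.character(classes),
                                   actual = as.character(classes)))
  structure(list(counts = counts, classes = classes),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = predicted, columns = actual\n")
  print(x$counts)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)` plus per-class one-vs-rest precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 (harmonic mean of the two) and
#' support, with macro averages. Division-by-zero cells yield 0 with the
#' corresponding `zero_division` flag set.
#'
#' @param cm a [confusion()] matrix.
#' @return An object of class `fit_report` with fields `accuracy`,
#'   `per_class` (data frame), `macro_precision`, `macro_recall`,
#'   `macro_f1`, `support_total`, `zero_division`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- cm$counts
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  k <- nrow(m)
  tp <- diag(m)
  fp <- rowSums(m) - tp   # predicted class i, actually something else
  fn <- colSums(m) - tp   # actually class i, predicted something else
  support <- colSums(m)
  flag <- logical(k)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  flag <- (tp + fp == 0) | (tp + fn == 0)
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  flag <- flag | (pr == 0)
  structure(list(
    accuracy = sum(tp) / total,
    per_class = data.frame(class = cm$classes, precision = precision,
                           recall = recall, f1 = f1, support = support,
                           row.names = NULL),
    macro_precision = mean(precision), macro_recall = mean(recall),
    macro_f1 = mean(f1), support_total = total, zero_division = flag,
    confusion = cm), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("<fit_report> accuracy:",
      formatC(x$accuracy, digits = 4, format = "f"))
  if (!is.null(x$cv_mean)) {
    cat("  cv:", formatC(x$cv_mean, digits = 4, format = "f"), "+/-",
        formatC(x$cv_sd, digits = 4, format = "f"))
  }
  cat("\n")
  print(x$per_class, digits = 4)
  invisible(x)
}

# stratified fold assignment: per class, shuffled then dealt round-robin
stratified_folds <- function(labels, k, seed) {
  rng <- rng_stream(seed, "cv_folds")
  fold <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class ", cl, " has ", length(idx), " members; need >= k = ", k)
    }
    fold[rng_shuffle(rng, idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into k stratified folds (per-class counts per fold within
#' one sample of proportionality), trains the model factory on each
#' training complement and scores accuracy on the held-out fold; reports the
#' fold mean (the cross-validation score) and standard deviation.
#'
#' @param model_factory `function(train_segment_set)` returning a fitted
#'   object `f` for which `predict_fn(f, test_segment_set)` gives labels.
#' @param s a [segment_set()].
#' @param k number of folds (10 by convention).
#' @param seed RNG seed for the fold assignment.
#' @param predict_fn prediction function; defaults to
#'   `predict(f, test, type = "class")`.
#' @return `list(cv_mean, cv_sd, fold_scores, fold_assignment)`.
#' @export
cross_validate <- function(model_factory, s, k = 10, seed = 1L,
                           predict_fn = NULL) {
  stopifnot(inherits(s, "segment_set"))
  predict_fn <- predict_fn %||%
    function(f, test) predict(f, test, type = "class")
  fold <- stratified_folds(s$labels, k, seed)
  scores <- numeric(k)
  for (fi in seq_len(k)) {
    train <- s[fold != fi]
    test <- s[fold == fi]
    fitted <- model_factory(train)
    pred <- predict_fn(fitted, test)
    scores[fi] <- mean(pred == test$labels)
  }
  list(cv_mean = mean(scores), cv_sd = stats::sd(scores),
       fold_scores = scores, fold_assignment = fold)
}

#' Comparison report table
#'
#' Collates evaluation results into the standard comparison layout: one row
#' per (model, condition) with accuracy, cross-validation mean +/- sd, and
#' per-class precision, all as percentages to two decimals.
#'
#' @param results a list of entries, each a list with `model`, `condition`,
#'   and a `fit_report` under `report` (optionally with `cv_mean`/`cv_sd`
#'   set).
#' @param file optional path; `.csv` or `.json` chosen by extension.
#' @return A data frame (invisibly written to `file` when given).
#' @export
report_table <- function(results, file = NULL) {
  if (!length(results)) stop("need at least one result")
  pct <- function(x) round(100 * x, 2)
  rows <- lapply(results, function(r) {
    rep_ <- r$report
    row <- data.frame(model = r$model,
                      condition = r$condition %||% "any",
                      accuracy_pct = pct(rep_$accuracy))
    row$cv_pct <- if (!is.null(rep_$cv_mean)) {
      paste0(formatC(pct(rep_$cv_mean), format = "f", digits = 2), " ± ",
             formatC(pct(rep_$cv_sd), format = "f", digits = 2))
    } else NA_character_
    for (ci in seq_len(nrow(rep_$per_class))) {
      row[[paste0("precision_", rep_$per_class$class[ci], "_pct")]] <-
        pct(rep_$per_class$precision[ci])
    }
    row
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(file)) {
    if (grepl("\\.json$", file)) {
      jsonlite::write_json(out, file, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null")
    } else {
      utils::write.csv(out, file, row.names = FALSE)
    }
  }
  out
}

#' 1-D Grad-CAM saliency map
#'
#' Gradient-weighted class activation mapping for 1-D convolutional models:
#' the gradient of the class score (pre-softmax logit) with respect to the
#' chosen convolutional layer's feature map is averaged over time to give
#' per-channel weights `w_k`; the map is `ReLU(sum_k w_k A_k)`, linearly
#' interpolated back to the input length and normalised to [0, 1] when its
#' maximum is positive.
#'
#' @param model a trained `eegcaps_model`.
#' @param segment a single segment: numeric vector, or 1-row matrix.
#' @param class_index column index of the class score (1..n_classes, in
#'   `model$class_levels` order).
#' @param layer name of a convolutional layer (e.g. `"conv6_3"`); defaults
#'   to the last conv layer.
#' @return An object of class `saliency_map`: `importance` (length = input
#'   length), `positions`, `layer`, `class_index`.
#' @export
gradcam_1d <- function(model, segment, class_index = 1L, layer = NULL) {
  stopifnot(inherits(model, "eegcaps_model"))
  signals <- if (is.matrix(segment)) segment else matrix(segment, 1)
  conv_names <- vapply(model$layers, function(l)
    if (l$type == "conv1d") l$name else NA_character_, "")
  conv_names <- conv_names[!is.na(conv_names)]
  layer <- layer %||% conv_names[length(conv_names)]
  li <- which(vapply(model$layers, function(l) l$name == layer, TRUE))
  if (!length(li)) {
    stop("no layer named '", layer, "'; convolutional layers: ",
         paste(conv_names, collapse = ", "))
  }
  li <- li[[1]]
  if (model$layers[[li]]$type != "conv1d") {
    stop("layer '", layer, "' is not convolutional; choose one of: ",
         paste(conv_names, collapse = ", "))
  }
  fw <- model_forward(model, signals_to_input(signals), training = FALSE,
                      keep_caches = TRUE, keep_outputs = TRUE)
  n_classes <- ncol(fw$logits)
  if (class_index < 1 || class_index > n_classes) {
    stop("class_index must be in 1..", n_classes)
  }
  dlogits <- matrix(0, 1, n_classes)
  dlogits[1, class_index] <- 1
  bw <- model_backward(model, fw$caches, dlogits, stop_at = li)
  A <- fw$outputs[[li]]        # [1, t_l, C]
  dA <- bw$dx
  t_l <- dim(A)[2]
  w <- colMeans(matrix(dA[1, , ], t_l))          # time-averaged gradient
  map <- as.vector(matrix(A[1, , ], t_l) %*% w)
  map <- pmax(map, 0)
  len <- ncol(signals)
  up <- if (t_l == 1) rep(map, len) else {
    stats::approx(seq(1, len, length.out = t_l), map, xout = seq_len(len))$y
  }
  if (max(up) > 0) up <- up / max(up)
  structure(list(importance = up, positions = seq_len(len), layer = layer,
                 class_index = class_index),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat("<saliency_map> layer:", x$layer, "| class:", x$class_index,
      "| length:", length(x$importance), "\n")
  invisible(x)
}

#' @export
as.data.frame.saliency_map <- function(x, ...) {
  data.frame(position = x$positions, importance = x$importance)
}
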