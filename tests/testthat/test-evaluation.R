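# Metrics, confusion matrices, cross-validation, reports, Grad-CAM.

test_that("confusion matrix uses predicted-rows x actual-columns", {
  cm <- confusion(c(1, 0, 1, 1), c(1, 0, 0, 1))
  # TP = 2 (pred 1, act 1), TN = 1, FP = 1 (pred 1, act 0), FN = 0
  expect_equal(cm$counts["1", "1"], 2L)
  expect_equal(cm$counts["0", "0"], 1L)
  expect_equal(cm$counts["1", "0"], 1L)
  expect_equal(cm$counts["0", "1"], 0L)

  diag_cm <- confusion(c(2, 3, 2), c(2, 3, 2))
  expect_true(all(diag_cm$counts[upper.tri(diag_cm$counts)] == 0))
  expect_true(all(diag_cm$counts[lower.tri(diag_cm$counts)] == 0))

  empty <- confusion(integer(0), integer(0), classes = 0:1)
  expect_true(all(empty$counts == 0))

  expect_error(confusion(1:3, 1:2), "length mismatch")
})

test_that("metrics reproduce the hand-tallied binary case", {
  # TP = 50, TN = 40, FP = 5, FN = 5
  pred <- c(rep(1, 50), rep(0, 40), rep(1, 5), rep(0, 5))
  act <- c(rep(1, 50), rep(0, 40), rep(0, 5), rep(1, 5))
  rep_ <- metrics(confusion(pred, act))
  expect_equal(rep_$accuracy, 0.90)
  pos <- rep_$per_class[rep_$per_class$class == 1, ]
  expect_equal(pos$precision, 50 / 55)
  expect_equal(pos$recall, 50 / 55)
  expect_equal(pos$f1, 50 / 55)  # precision == recall => F1 equals both
  expect_equal(pos$support, 55)
  expect_equal(rep_$support_total, 100)
})

test_that("metrics handle perfect and degenerate predictions", {
  perfect <- metrics(confusion(c(1, 2, 3, 1), c(1, 2, 3, 1)))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$precision == 1))
  expect_true(all(perfect$per_class$f1 == 1))

  # classifier never predicts the positive class
  deg <- metrics(confusion(rep(0, 10), c(rep(0, 7), rep(1, 3))))
  pos <- deg$per_class[deg$per_class$class == 1, ]
  expect_equal(pos$precision, 0)
  expect_equal(pos$recall, 0)
  expect_true(any(deg$zero_division))
})

test_that("metrics agree with the caret reference on random cases", {
  skip_if_not_installed("caret")
  set.seed(20)
  for (case in 1:100) {
    k <- sample(2:5, 1)
    n <- sample(30:80, 1)
    act <- sample(seq_len(k), n, replace = TRUE)
    pred <- ifelse(stats::runif(n) < 0.6, act,
                   sample(seq_len(k), n, replace = TRUE))
    classes <- seq_len(k)
    rep_ <- metrics(confusion(pred, act, classes = classes))
    ref <- caret::confusionMatrix(factor(pred, classes),
                                  factor(act, classes))
    expect_equal(rep_$accuracy, unname(ref$overall["Accuracy"]),
                 tolerance = 1e-12)
    by_class <- if (k == 2) {
      matrix(ref$byClass, 1, length(ref$byClass),
             dimnames = list(NULL, names(ref$byClass)))
    } else ref$byClass
    for (ci in seq_len(k)) {
      ref_prec <- by_class[if (k == 2) 1 else ci, "Precision"]
      ref_rec <- by_class[if (k == 2) 1 else ci, "Sensitivity"]
      ref_f1 <- by_class[if (k == 2) 1 else ci, "F1"]
      mine <- rep_$per_class[ci, ]
      if (k == 2 && ci == 2) break  # caret reports the positive class only
      if (!is.na(ref_prec)) expect_equal(mine$precision, unname(ref_prec),
                                         tolerance = 1e-12)
      if (!is.na(ref_rec)) expect_equal(mine$recall, unname(ref_rec),
                                        tolerance = 1e-12)
      if (!is.na(ref_f1)) expect_equal(mine$f1, unname(ref_f1),
                                       tolerance = 1e-12)
    }
  }
})

test_that("stratified cross-validation matches the closed form for a
           constant classifier", {
  s <- segment_set(matrix(rnorm(400), 100, 4),
                   c(rep(0L, 90), rep(1L, 10)), label_scheme = "binary")
  majority <- function(train) {
    structure(list(), class = "majority_clf")
  }
  pred_major <- function(f, test) rep(0L, n_segments(test))
  cv <- cross_validate(majority, s, k = 10, seed = 3,
                       predict_fn = pred_major)
  # stratified folds hold 9 majority + 1 minority each: accuracy 0.9 per fold
  expect_equal(cv$cv_mean, 0.9, tolerance = 1e-12)
  expect_equal(cv$cv_sd, 0)
  expect_equal(length(cv$fold_scores), 10)
})

test_that("cross-validation folds partition the data with balanced strata", {
  s <- toy_segments(103, 5, labels = c(rep(1L, 52), rep(2L, 51)))
  cv <- cross_validate(function(train) structure(list(), class = "x"), s,
                       k = 5, seed = 2,
                       predict_fn = function(f, te) te$labels)
  fold <- cv$fold_assignment
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 103)
  for (cl in 1:2) {
    counts <- table(fold[s$labels == cl])
    expect_lte(max(counts) - min(counts), 1)
  }
  expect_equal(cv$cv_mean, 1)  # oracle predictor
})

test_that("leave-one-out produces n folds", {
  s <- segment_set(matrix(rnorm(80), 20, 4), rep(1L, 20))
  cv <- cross_validate(function(train) structure(list(), class = "x"), s,
                       k = 20, seed = 1,
                       predict_fn = function(f, te) te$labels)
  expect_equal(length(cv$fold_scores), 20)
  expect_equal(cv$cv_sd, 0)  # identical per-fold scores

  small <- toy_segments(12, 4, labels = rep(1:2, 6))
  expect_error(cross_validate(function(x) x, small, k = 10), "need >= k")
})

test_that("report table follows the comparison layout", {
  rep1 <- metrics(confusion(c(1, 1, 0, 0), c(1, 0, 0, 0)))
  rep1$cv_mean <- 0.75
  rep1$cv_sd <- 0.05
  rep2 <- metrics(confusion(c(1, 0, 1, 1), c(1, 0, 1, 1)))
  out <- report_table(list(
    list(model = "SVM", condition = "scaling", report = rep1),
    list(model = "cnn_caps", condition = "any", report = rep2)))
  expect_equal(nrow(out), 2)
  expect_true(all(c("model", "condition", "accuracy_pct", "cv_pct",
                    "precision_0_pct", "precision_1_pct") %in% names(out)))
  expect_equal(out$accuracy_pct, c(75, 100))
  expect_match(out$cv_pct[1], "75.00 ± 5.00")

  csv <- tempfile(fileext = ".csv")
  report_table(list(list(model = "SVM", report = rep1)), file = csv)
  expect_true(file.exists(csv))
  expect_error(report_table(list()), "at least one")
})

test_that("gradcam matches the analytic map of a tiny linear network", {
  # conv with center-tap kernels A_1 = x, A_2 = 2x; linear head on the
  # global max pool with known weights. The class-score gradient w.r.t.
  # A_k is W[k, class] at the argmax position, so w_k = W[k, class] / t and
  # map = relu((W[1, c] * x + W[2, c] * 2x) / t), then normalised.
  rng <- eegcaps:::rng_stream(1, "gc")
  conv <- eegcaps:::layer_conv1d(rng, "conv1_1", 1, 2)
  conv$params$W <- matrix(c(0, 1, 0,   0, 2, 0), 3, 2)
  conv$params$b <- c(0, 0)
  dense <- eegcaps:::layer_dense(rng, "fc_out", 2, 2)
  Wd <- matrix(c(0.5, -1, 2, 1), 2, 2)
  dense$params$W <- Wd
  dense$params$b <- c(0, 0)
  model <- structure(list(layers = list(conv,
                                        eegcaps:::layer_gmaxpool("g"),
                                        dense),
                          pos_enc = NULL, class_levels = c(0L, 1L)),
                     class = "eegcaps_model")
  x <- c(0.3, -1.2, 2.0, 0.5, -0.4, 1.5)
  t_ <- length(x)
  for (cls in 1:2) {
    sal <- gradcam_1d(model, x, class_index = cls, layer = "conv1_1")
    w <- Wd[, cls] / t_
    expected <- pmax(w[1] * x + w[2] * 2 * x, 0)
    if (max(expected) > 0) expected <- expected / max(expected)
    expect_equal(sal$importance, expected, tolerance = 1e-10)
    expect_equal(length(sal$importance), t_)
  }
  expect_error(gradcam_1d(model, x, layer = "nope"), "conv1_1")
  df <- as.data.frame(gradcam_1d(model, x, 1, "conv1_1"))
  expect_equal(names(df), c("position", "importance"))
})

test_that("gradcam maps span the input length on a real model", {
  spec <- architecture_spec("cnn_fully", input_len = 64, n_classes = 2,
                            width_scale = 16, seed = 2)
  model <- suppressMessages(build_model(spec))
  model$class_levels <- c(0L, 1L)
  x <- rnorm(64)
  sal <- gradcam_1d(model, x, class_index = 1)
  expect_equal(length(sal$importance), 64)
  expect_true(all(sal$importance >= 0 & sal$importance <= 1))
})
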