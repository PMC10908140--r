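# Thin comparison harness over classical classifiers.
#
# Estimator math is delegated to the established packages (rpart, nnet,
# ranger, e1071, randomForest, xgboost); this module only supplies
# orchestration: pipelines over segment sets, exhaustive grid search with
# stratified 10-fold CV, and impurity-based feature-importance reporting.
# Two estimators have no installed equivalent and are implemented here in a
# few lines each: a Minkowski-p brute-force k-nearest-neighbour predictor
# and a hinge-loss linear classifier trained by stochastic gradient descent
# (with l1/l2/elasticnet penalties).

CLASSIC_ALGOS <- c("DTC", "MLP", "KNN", "SGDC", "ETC", "SVM", "RFC", "GB")

#' Grid-search specification for a classical classifier
#'
#' @param algorithm one of DTC (decision tree), MLP (multilayer perceptron),
#'   KNN (k-nearest neighbours), SGDC (SGD linear classifier), ETC (extra
#'   trees), SVM, RFC (random forest), GB (gradient boosting).
#' @param grid named list mapping hyperparameter names to candidate value
#'   vectors/lists; defaults to [default_grid()] for the algorithm.
#' @param cv_folds folds for the inner cross-validation (10 by convention).
#' @param seed RNG seed (fold assignment and stochastic fits).
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(algorithm, grid = NULL, cv_folds = 10, seed = 1L) {
  if (!algorithm %in% CLASSIC_ALGOS) {
    stop("unsupported algorithm '", algorithm, "'; supported: ",
         paste(CLASSIC_ALGOS, collapse = ", "))
  }
  grid <- grid %||% default_grid(algorithm)
  if (!length(grid)) stop("grid must be non-empty")
  structure(list(algorithm = algorithm, grid = grid,
                 cv_folds = cv_folds, seed = as.integer(seed)),
            class = "grid_spec")
}

#' Default hyperparameter grids
#'
#' Each grid contains the reference tuned value for the task plus a
#' neighbouring value on each side where meaningful, so every reported best
#' configuration is representable and searchable.
#'
#' @param algorithm algorithm code (see [grid_spec()]).
#' @param task `"binary"`, `"multiclass"`, `"smote"` or `"adasyn"` — which
#'   tuned configuration to centre the grid on.
#' @return Named list of candidate values.
#' @export
default_grid <- function(algorithm,
                         task = c("binary", "multiclass", "smote",
                                  "adasyn")) {
  task <- match.arg(task)
  pick <- function(binary, multiclass, smote = binary, adasyn = smote) {
    switch(task, binary = binary, multiclass = multiclass, smote = smote,
           adasyn = adasyn)
  }
  switch(algorithm,
    DTC = list(
      criterion = unique(c(pick("entropy", "gini", "entropy"), "gini",
                           "entropy")),
      max_depth = list(NULL, 10),
      min_samples_leaf = unique(c(pick(4, 2, 1), 1, 2, 4)),
      min_samples_split = unique(c(pick(10, 10, 2), 2, 10))),
    MLP = list(
      activation = unique(c(pick("logistic", "relu", "relu"), "relu")),
      hidden_layer_sizes = unique(list(pick(list(100), list(100, 50),
                                            list(100, 50))[[1]],
                                       list(100), list(100, 50), list(50))),
      learning_rate = unique(c(pick("constant", "constant", "constant",
                                    "adaptive"), "constant")),
      solver = list("adam")),
    KNN = list(
      algorithm = list("auto"),
      leaf_size = list(1),
      n_neighbors = c(1, 3, 5),
      p = c(1, 2),
      weights = list("uniform")),
    SGDC = list(
      alpha = unique(c(pick(0.001, 0.01, 0.001), 0.001, 0.01)),
      loss = list("hinge"),
      max_iter = unique(c(pick(2000, 1000, 3000), 1000)),
      penalty = unique(c(pick("l2", "l1", "elasticnet", "l2"), "l1", "l2",
                         "elasticnet"))),
    ETC = list(
      min_samples_split = unique(c(pick(4, 2, 2), 2, 4)),
      n_estimators = unique(c(pick(150, 300, 150, 300), 150, 300)),
      random_state = unique(c(pick(20, 20, 40, 50), 20))),
    SVM = list(
      C = c(1, 10, 100),
      gamma = list("scale", "auto"),
      kernel = list("rbf")),
    RFC = list(
      max_depth = list(NULL),
      min_samples_split = unique(c(pick(2, 2, 4), 2, 4)),
      n_estimators = unique(c(pick(500, 500, 150), 150, 500)),
      random_state = unique(c(pick(40, 40, 30), 40))),
    GB = list(
      learning_rate = c(0.1, 0.3),
      max_depth = unique(c(pick(5, 7, 7), 5, 7)),
      n_estimators = c(100, 200),
      random_state = unique(c(pick(40, 10, 40), 40))),
    stop("unsupported algorithm '", algorithm, "'"))
}

# ---- backends -------------------------------------------------------------

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("package '", pkg, "' is required for this classifier")
  }
}

fit_classical <- function(algorithm, params, train, seed = 1L) {
  x <- train$signals
  y <- factor(train$labels)
  df <- data.frame(y = y, x)
  p <- ncol(x)
  est <- switch(algorithm,
    DTC = {
      need_pkg("rpart")
      split <- if (identical(params$criterion, "entropy")) "information"
               else "gini"
      rpart::rpart(y ~ ., data = df, method = "class",
                   parms = list(split = split),
                   control = rpart::rpart.control(
                     minsplit = params$min_samples_split %||% 2,
                     minbucket = params$min_samples_leaf %||% 1,
                     maxdepth = min(30, params$max_depth %||% 30),
                     cp = 0, xval = 0))
    },
    MLP = {
      need_pkg("nnet")
      sizes <- unlist(params$hidden_layer_sizes %||% 100)
      set.seed(seed)
      # nnet fits a single logistic hidden layer; the first stated width is
      # used and remaining configuration is recorded with the fit
      nnet::nnet(x, nnet::class.ind(y), size = sizes[1], softmax = TRUE,
                 maxit = 200, MaxNWts = 1e6, trace = FALSE)
    },
    KNN = knn_fit(x, y, k = params$n_neighbors %||% 1,
                  p = params$p %||% 2),
    SGDC = sgd_fit(x, y, alpha = params$alpha %||% 1e-3,
                   penalty = params$penalty %||% "l2",
                   max_iter = params$max_iter %||% 1000, seed = seed),
    ETC = {
      need_pkg("ranger")
      ranger::ranger(y ~ ., data = df,
                     num.trees = params$n_estimators %||% 300,
                     splitrule = "extratrees",
                     min.node.size = params$min_samples_split %||% 2,
                     importance = "impurity",
                     seed = params$random_state %||% seed,
                     num.threads = 1)
    },
    SVM = {
      need_pkg("e1071")
      gamma <- params$gamma %||% "scale"
      gval <- if (identical(gamma, "scale")) 1 / (p * stats::var(as.vector(x)))
              else if (identical(gamma, "auto")) 1 / p else gamma
      e1071::svm(x, y, cost = params$C %||% 10, gamma = gval,
                 kernel = "radial")
    },
    RFC = {
      need_pkg("randomForest")
      set.seed(params$random_state %||% seed)
      randomForest::randomForest(
        x, y, ntree = params$n_estimators %||% 500,
        nodesize = params$min_samples_split %||% 1)
    },
    GB = {
      need_pkg("xgboost")
      k <- nlevels(y)
      yv <- as.integer(y) - 1L
      xgb_params <- list(eta = params$learning_rate %||% 0.1,
                         max_depth = params$max_depth %||% 6,
                         nthread = 1,
                         seed = params$random_state %||% seed)
      if (k > 2) {
        xgb_params <- c(xgb_params,
                        list(objective = "multi:softmax", num_class = k))
      } else {
        xgb_params <- c(xgb_params, list(objective = "binary:logistic"))
      }
      xgboost::xgb.train(params = xgb_params,
                         data = xgboost::xgb.DMatrix(x, label = yv),
                         nrounds = params$n_estimators %||% 200)
    },
    stop("unsupported algorithm '", algorithm, "'"))
  structure(list(algorithm = algorithm, estimator = est,
                 levels = levels(y), params = params, n_features = p),
            class = "classical_fit")
}

#' @export
predict.classical_fit <- function(object, s, ...) {
  x <- if (inherits(s, "segment_set")) s$signals else as.matrix(s)
  est <- object$estimator
  lv <- object$levels
  out <- switch(object$algorithm,
    DTC = {
      cls <- predict(est, data.frame(x), type = "class")
      as.character(cls)
    },
    MLP = lv[max.col(predict(est, x), ties.method = "first")],
    KNN = knn_predict(est, x),
    SGDC = sgd_predict(est, x),
    ETC = as.character(predict(est, data.frame(x))$predictions),
    SVM = as.character(predict(est, x)),
    RFC = as.character(predict(est, x)),
    GB = {
      pr <- predict(est, xgboost::xgb.DMatrix(x))
      if (length(lv) > 2) lv[pr + 1L]
      else lv[as.integer(pr > 0.5) + 1L]
    })
  as.integer(out)
}

# brute-force k-nearest neighbours with Minkowski-p distance, uniform vote
knn_fit <- function(x, y, k = 1, p = 2) {
  list(x = x, y = y, k = k, p = p)
}

knn_predict <- function(fit, newx) {
  n <- nrow(newx)
  out <- character(n)
  if (fit$p == 2) {
    d <- pairwise_sqdist(newx, fit$x)
  } else {
    d <- matrix(0, n, nrow(fit$x))
    tx <- t(fit$x)
    for (i in seq_len(n)) {
      d[i, ] <- colSums(abs(tx - newx[i, ])^fit$p)
    }
  }
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(fit$k)]
    votes <- table(fit$y[nb])
    out[i] <- names(votes)[which.max(votes)]
  }
  out
}

# hinge-loss linear classifier by SGD (one-vs-rest for > 2 classes);
# learning schedule eta_t = 1 / (alpha * (t0 + t)), elasticnet ratio 0.15
sgd_fit <- function(x, y, alpha = 1e-3, penalty = "l2", max_iter = 1000,
                    seed = 1L, l1_ratio = 0.15) {
  lv <- levels(y)
  rng <- rng_stream(seed, "sgdc")
  scale_ <- list(mean = colMeans(x),
                 sd = apply(x, 2, stats::sd) + 1e-12)
  xs <- sweep(sweep(x, 2, scale_$mean), 2, scale_$sd, "/")
  fit_one <- function(pos) {
    yy <- ifelse(y == pos, 1, -1)
    w <- rep(0, ncol(xs)); b <- 0
    t <- 1
    epochs <- max(1, min(50, ceiling(max_iter / 20)))
    for (ep in seq_len(epochs)) {
      for (i in rng_shuffle(rng, seq_len(nrow(xs)))) {
        eta <- 1 / (alpha * (1e3 + t))
        margin <- yy[i] * (sum(w * xs[i, ]) + b)
        gpen <- switch(penalty,
          l2 = alpha * w,
          l1 = alpha * sign(w),
          elasticnet = alpha * (l1_ratio * sign(w) + (1 - l1_ratio) * w),
          stop("unknown penalty '", penalty, "'"))
        gw <- gpen
        gb <- 0
        if (margin < 1) {
          gw <- gw - yy[i] * xs[i, ]
          gb <- -yy[i]
        }
        w <- w - eta * gw
        b <- b - eta * gb
        t <- t + 1
      }
    }
    list(w = w, b = b)
  }
  list(models = lapply(lv, fit_one), levels = lv, scale = scale_)
}

sgd_predict <- function(fit, newx) {
  xs <- sweep(sweep(newx, 2, fit$scale$mean), 2, fit$scale$sd, "/")
  scores <- vapply(fit$models, function(m) as.vector(xs %*% m$w + m$b),
                   numeric(nrow(xs)))
  scores <- matrix(scores, nrow(xs))
  fit$levels[max.col(scores, ties.method = "first")]
}

# ---- grid search ----------------------------------------------------------

grid_combinations <- function(grid) {
  idx <- expand.grid(lapply(grid, seq_along), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(idx)), function(r) {
    combo <- lapply(seq_along(grid), function(ci) {
      v <- grid[[ci]]
      if (is.list(v)) v[[idx[r, ci]]] else v[idx[r, ci]]
    })
    names(combo) <- names(grid)
    combo
  })
}

#' Exhaustive grid search with stratified k-fold cross-validation
#'
#' Evaluates every hyperparameter combination by stratified k-fold CV
#' accuracy, picks the best (ties broken by grid order, so results are
#' deterministic under a fixed seed), and refits it on the full training
#' set.
#'
#' @param spec a [grid_spec()].
#' @param train a [segment_set()].
#' @return A list of class `grid_fit`: `best_params`, `best_cv_accuracy`,
#'   `estimator` (refit on all of `train`), and `results` (one row per
#'   combination).
#' @export
grid_search_fit <- function(spec, train) {
  stopifnot(inherits(spec, "grid_spec"), inherits(train, "segment_set"))
  combos <- grid_combinations(spec$grid)
  scores <- numeric(length(combos))
  for (ci in seq_along(combos)) {
    params <- combos[[ci]]
    cv <- cross_validate(
      function(tr) fit_classical(spec$algorithm, params, tr,
                                 seed = spec$seed),
      train, k = spec$cv_folds, seed = spec$seed,
      predict_fn = function(f, te) predict(f, te))
    scores[ci] <- cv$cv_mean
  }
  best <- which.max(scores)
  results <- data.frame(
    combo = seq_along(combos),
    cv_accuracy = scores,
    params = vapply(combos, function(p)
      paste(names(p), vapply(p, function(v)
        paste(deparse(v), collapse = ""), ""), sep = "=", collapse = ", "),
      ""))
  structure(list(algorithm = spec$algorithm,
                 best_params = combos[[best]],
                 best_cv_accuracy = scores[best],
                 estimator = fit_classical(spec$algorithm, combos[[best]],
                                           train, seed = spec$seed),
                 results = results),
            class = "grid_fit")
}

#' @export
predict.grid_fit <- function(object, s, ...) predict(object$estimator, s)

#' @export
print.grid_fit <- function(x, ...) {
  cat("<grid_fit>", x$algorithm, "| best CV accuracy:",
      formatC(x$best_cv_accuracy, digits = 4, format = "f"), "\n")
  cat("  best params:", x$results$params[which.max(x$results$cv_accuracy)],
      "\n")
  invisible(x)
}

#' Impurity-based feature importance of a fitted tree ensemble
#'
#' Extracts per-feature impurity importances (normalised to sum 1 over all
#' features) and returns the `top_n` features in descending order — the
#' "most crucial points" of the input segment for the ensemble.
#'
#' @param fit a `grid_fit` or `classical_fit` for a tree ensemble (ETC, RFC,
#'   GB or DTC).
#' @param top_n number of top features to return.
#' @return Data frame with `feature` (1-based input position) and
#'   `importance`, sorted descending.
#' @export
feature_importance <- function(fit, top_n = 30) {
  if (inherits(fit, "grid_fit")) fit <- fit$estimator
  if (!inherits(fit, "classical_fit")) {
    stop("expected a classical_fit or grid_fit")
  }
  p <- fit$n_features
  imp <- rep(0, p)
  est <- fit$estimator
  raw <- switch(fit$algorithm,
    ETC = ranger::importance(est),
    RFC = randomForest::importance(est)[, 1],
    DTC = est$variable.importance,
    GB = {
      m <- xgboost::xgb.importance(model = est)
      # unnamed training matrices yield 0-based "f<idx>" feature labels
      stats::setNames(m$Gain,
                      as.integer(sub("^f", "", m$Feature)) + 1L)
    },
    stop("estimator '", fit$algorithm,
         "' does not expose impurity-based importances; use one of ",
         "DTC, ETC, RFC, GB"))
  if (is.null(raw)) raw <- numeric(0)
  feat_idx <- as.integer(sub("^[VX]", "", names(raw)))
  ok <- !is.na(feat_idx) & feat_idx >= 1 & feat_idx <= p
  imp[feat_idx[ok]] <- raw[ok]
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)[seq_len(min(top_n, p))]
  data.frame(feature = ord, importance = imp[ord])
}
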