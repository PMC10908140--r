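#' Fit a per-feature standard scaler on training data
#'
#' Computes per-column mean and population (1/n) standard deviation of the
#' training signals. Transformation is `(x - mean) / (sd + epsilon)`;
#' zero-variance features map to 0 via the epsilon stabiliser.
#'
#' @param train a [segment_set()] with at least 2 segments.
#' @param epsilon small positive stabiliser added to sd.
#' @return A list of class `scaler_params` with `mean`, `sd`, `epsilon`.
#' @export
fit_scaler <- function(train, epsilon = 1e-12) {
  stopifnot(inherits(train, "segment_set"))
  if (n_segments(train) < 2) stop("need >= 2 segments to fit a scaler")
  m <- colMeans(train$signals)
  v <- colMeans(sweep(train$signals, 2, m)^2)  # population variance
  structure(list(mean = m, sd = sqrt(v), epsilon = epsilon),
            class = "scaler_params")
}

#' Apply a fitted standard scaler
#'
#' @param p a `scaler_params` from [fit_scaler()].
#' @param s a [segment_set()] of matching segment length.
#' @return The standardised [segment_set()]; labels unchanged.
#' @export
apply_scaler <- function(p, s) {
  stopifnot(inherits(p, "scaler_params"), inherits(s, "segment_set"))
  if (ncol(s$signals) != length(p$mean)) {
    stop("segment_len mismatch: scaler fit on ", length(p$mean),
         " features, data has ", ncol(s$signals))
  }
  x <- sweep(s$signals, 2, p$mean)
  x <- sweep(x, 2, p$sd + p$epsilon, "/")
  out <- s
  out$signals <- x
  out
}

#' Fit principal component analysis on training data
#'
#' Centered PCA via singular value decomposition; the top `n_components`
#' directions by descending variance. Component signs are fixed
#' deterministically (the largest-magnitude loading of each component is
#' made positive) so runs are reproducible.
#'
#' @param train a [segment_set()].
#' @param n_components number of components to keep (40 by convention, the
#'   width the downstream models expect for the reduced input).
#' @return A list of class `pca_params` with orthonormal `components`
#'   (`n_components x segment_len`), `center`, and non-increasing
#'   `explained_variance` (population scale).
#' @export
fit_pca <- function(train, n_components = 40) {
  stopifnot(inherits(train, "segment_set"))
  n <- n_segments(train)
  p <- ncol(train$signals)
  if (n_components > min(n, p)) {
    stop("n_components (", n_components, ") exceeds min(n_segments, ",
         "segment_len) = ", min(n, p))
  }
  center <- colMeans(train$signals)
  xc <- sweep(train$signals, 2, center)
  sv <- svd(xc, nu = 0, nv = n_components)
  comps <- t(sv$v)  # rows are components
  # deterministic sign: largest-|loading| entry positive
  for (k in seq_len(nrow(comps))) {
    j <- which.max(abs(comps[k, ]))
    if (comps[k, j] < 0) comps[k, ] <- -comps[k, ]
  }
  structure(list(components = comps, center = center,
                 explained_variance = (sv$d[seq_len(n_components)]^2) / n,
                 n_components = n_components),
            class = "pca_params")
}

#' Project data onto fitted principal components
#'
#' @param p a `pca_params` from [fit_pca()].
#' @param s a [segment_set()] of matching width.
#' @return A [segment_set()] whose segment length is `n_components`.
#' @export
apply_pca <- function(p, s) {
  stopifnot(inherits(p, "pca_params"), inherits(s, "segment_set"))
  if (ncol(s$signals) != length(p$center)) {
    stop("width mismatch: PCA fit on ", length(p$center),
         " features, data has ", ncol(s$signals))
  }
  out <- s
  out$signals <- sweep(s$signals, 2, p$center) %*% t(p$components)
  out
}

#' Apply one of the four dataset conditions
#'
#' The four preprocessing conditions under which every model is evaluated:
#' `"any"` (no preprocessing), `"scaling"` (per-feature standardisation),
#' `"pca"` (projection to `n_components` principal components), and
#' `"scaling_pca"` (standardisation followed by PCA). All parameters are fit
#' on `train` only and applied unchanged to the remaining sets.
#'
#' @param name condition name.
#' @param train training [segment_set()] (parameters are fit here).
#' @param ... further segment sets (e.g. test) transformed with the
#'   train-fitted parameters.
#' @param n_components PCA width for the pca conditions.
#' @return `list(train = , ... , params = )`; `params` holds the fitted
#'   `scaler_params` / `pca_params` (NULL for `"any"`).
#' @export
condition_pipeline <- function(name, train, ..., n_components = 40) {
  valid <- c("any", "scaling", "pca", "scaling_pca")
  if (!name %in% valid) {
    stop("unknown condition '", name, "'; valid: ",
         paste(valid, collapse = ", "))
  }
  others <- list(...)
  params <- list()
  sets <- c(list(train = train), others)
  if (name %in% c("scaling", "scaling_pca")) {
    params$scaler <- fit_scaler(train)
    sets <- lapply(sets, function(s) apply_scaler(params$scaler, s))
  }
  if (name %in% c("pca", "scaling_pca")) {
    params$pca <- fit_pca(sets$train, n_components = n_components)
    sets <- lapply(sets, function(s) apply_pca(params$pca, s))
  }
  c(sets, list(params = if (length(params)) params else NULL))
}

#' Serialise fitted preprocessing parameters to JSON
#'
#' @param params a `scaler_params` or `pca_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_params_json <- function(params, path) {
  kind <- class(params)[1]
  payload <- list(kind = kind, fields = unclass(params))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load preprocessing parameters saved by [save_params_json()]
#'
#' @param path JSON file path.
#' @return The restored parameter object.
#' @export
load_params_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- payload$fields
  if (payload$kind == "pca_params" && is.list(fields$components)) {
    fields$components <- do.call(rbind, fields$components)
  }
  if (!is.null(fields$components)) {
    fields$components <- as.matrix(fields$components)
  }
  structure(fields, class = payload$kind)
}
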