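#' Oversampling configuration for SMOTE / ADASYN
#'
#' @param k_neighbors neighbours considered when interpolating (canonical 5).
#' @param target_ratio desired minority:majority ratio after balancing.
#' @param seed integer RNG seed.
#' @return A list of class `oversample_config`.
#' @export
oversample_config <- function(k_neighbors = 5, target_ratio = 1.0, seed = 1L) {
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  if (target_ratio <= 0 || target_ratio > 1) {
    stop("target_ratio must be in (0, 1]")
  }
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_ratio = target_ratio, seed = as.integer(seed)),
            class = "oversample_config")
}

# squared Euclidean distances from rows of a to rows of b
pairwise_sqdist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}

# indices (into rows of pool) of the k nearest neighbours of each row of x;
# self-matches excluded when exclude_self
knn_index <- function(x, pool, k, exclude_self = FALSE) {
  d <- pairwise_sqdist(x, pool)
  if (exclude_self) diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

balance_checks <- function(s, cfg) {
  stopifnot(inherits(s, "segment_set"), inherits(cfg, "oversample_config"))
  if (s$label_scheme != "binary") {
    stop("oversampling expects a binary segment_set")
  }
  tab <- table(factor(s$labels, levels = 0:1))
  if (any(tab == 0)) stop("both classes must be present")
  minority <- if (tab[["1"]] <= tab[["0"]]) 1L else 0L
  n_min <- min(tab)
  if (n_min <= cfg$k_neighbors) {
    stop("minority count (", n_min, ") must exceed k_neighbors (",
         cfg$k_neighbors, "); use a smaller k")
  }
  minority
}

# number of synthetic points needed for target_ratio
synth_needed <- function(n_min, n_maj, ratio) {
  max(0L, as.integer(round(ratio * n_maj)) - n_min)
}

append_synth <- function(s, synth, label) {
  segment_set(rbind(s$signals, synth),
              c(s$labels, rep(label, nrow(synth))),
              label_scheme = "binary", class_names = s$class_names,
              sampling_rate = s$sampling_rate)
}

#' SMOTE: synthetic minority over-sampling by interpolation
#'
#' For each required synthetic point a minority sample `x` is taken
#' (round-robin over a shuffled minority ordering), one of its `k` nearest
#' minority neighbours `x_n` (Euclidean) is drawn, and the synthetic point is
#' `x + u * (x_n - x)` with `u ~ Uniform(0, 1)` — a point on the segment
#' joining the pair. Original rows are preserved untouched; synthetics are
#' appended until the minority:majority ratio reaches `target_ratio`.
#'
#' @param s a binary [segment_set()] with both classes present.
#' @param cfg an [oversample_config()].
#' @return The augmented binary [segment_set()].
#' @export
smote <- function(s, cfg = oversample_config()) {
  minority <- balance_checks(s, cfg)
  min_idx <- which(s$labels == minority)
  n_min <- length(min_idx)
  n_maj <- n_segments(s) - n_min
  G <- synth_needed(n_min, n_maj, cfg$target_ratio)
  if (G == 0) return(s)

  X <- s$signals[min_idx, , drop = FALSE]
  nn <- knn_index(X, X, cfg$k_neighbors, exclude_self = TRUE)
  rng <- rng_stream(cfg$seed, "smote")
  order_min <- rng_shuffle(rng, seq_len(n_min))
  synth <- matrix(0, G, ncol(X))
  for (g in seq_len(G)) {
    i <- order_min[((g - 1L) %% n_min) + 1L]
    j <- nn[i, rng_sample(rng, seq_len(cfg$k_neighbors), 1)]
    u <- rng_runif(rng, 1)
    synth[g, ] <- X[i, ] + u * (X[j, ] - X[i, ])
  }
  append_synth(s, synth, minority)
}

#' ADASYN: adaptive synthetic sampling of the minority class
#'
#' Synthetic generation is focused where the minority class is hardest to
#' learn: for each minority point `x_i`, the fraction `r_i = Delta_i / k` of
#' majority points among its `k` nearest neighbours (over the full dataset)
#' is computed; the normalised `r_i` allocate the `G` required synthetics, so
#' boundary points (surrounded by majority) seed more synthetics than
#' interior points. If every `r_i` is zero the allocation falls back to
#' uniform. Each synthetic interpolates from its seed toward one of the
#' seed's `k` nearest minority neighbours, as in SMOTE. Rounding residue is
#' assigned one-by-one to the highest-`r_i` seeds.
#'
#' @inheritParams smote
#' @return The augmented binary [segment_set()].
#' @export
adasyn <- function(s, cfg = oversample_config()) {
  minority <- balance_checks(s, cfg)
  min_idx <- which(s$labels == minority)
  n_min <- length(min_idx)
  n_maj <- n_segments(s) - n_min
  G <- synth_needed(n_min, n_maj, cfg$target_ratio)
  if (G == 0) return(s)

  X <- s$signals[min_idx, , drop = FALSE]
  k <- cfg$k_neighbors
  # Delta_i: majority neighbours among k nearest over the full set
  d_full <- pairwise_sqdist(X, s$signals)
  d_full[cbind(seq_len(n_min), min_idx)] <- Inf  # exclude self
  r <- apply(d_full, 1, function(row) {
    nb <- order(row)[seq_len(k)]
    sum(s$labels[nb] != minority) / k
  })
  if (sum(r) == 0) {
    r_hat <- rep(1 / n_min, n_min)
  } else {
    r_hat <- r / sum(r)
  }
  g_i <- as.integer(round(r_hat * G))
  residue <- G - sum(g_i)
  if (residue != 0) {
    pick <- order(r_hat, decreasing = TRUE)
    step <- if (residue > 0) 1L else -1L
    i <- 1L
    while (residue != 0) {
      j <- pick[((i - 1L) %% n_min) + 1L]
      if (step > 0 || g_i[j] > 0) {
        g_i[j] <- g_i[j] + step
        residue <- residue - step
      }
      i <- i + 1L
    }
  }

  nn_min <- knn_index(X, X, k, exclude_self = TRUE)
  rng <- rng_stream(cfg$seed, "adasyn")
  synth <- matrix(0, G, ncol(X))
  g <- 1L
  for (i in seq_len(n_min)) {
    for (rep in seq_len(g_i[i])) {
      j <- nn_min[i, rng_sample(rng, seq_len(k), 1)]
      u <- rng_runif(rng, 1)
      synth[g, ] <- X[i, ] + u * (X[j, ] - X[i, ])
      g <- g + 1L
    }
  }
  out <- append_synth(s, synth, minority)
  attr(out, "adasyn_allocation") <- g_i
  out
}
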