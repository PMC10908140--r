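# Naive reference implementations used as independent oracles, plus small
# fixture builders. These deliberately mirror the written definitions with
# plain loops and stay independent of the package's vectorised code paths.

# routing-by-agreement as a literal triple loop over (i, j, iterations)
naive_routing <- function(u_hat, r) {
  n_in <- dim(u_hat)[1]; n_out <- dim(u_hat)[2]; d <- dim(u_hat)[3]
  b <- matrix(0, n_in, n_out)
  v <- matrix(0, n_out, d)
  cc <- matrix(0, n_in, n_out)
  for (it in seq_len(r)) {
    for (i in seq_len(n_in)) {
      e <- exp(b[i, ] - max(b[i, ]))
      cc[i, ] <- e / sum(e)
    }
    for (j in seq_len(n_out)) {
      s_j <- rep(0, d)
      for (i in seq_len(n_in)) {
        s_j <- s_j + cc[i, j] * u_hat[i, j, ]
      }
      n2 <- sum(s_j^2)
      v[j, ] <- if (n2 == 0) rep(0, d) else {
        (n2 / (1 + n2)) * s_j / sqrt(n2)
      }
    }
    for (i in seq_len(n_in)) {
      for (j in seq_len(n_out)) {
        b[i, j] <- b[i, j] + sum(u_hat[i, j, ] * v[j, ])
      }
    }
  }
  list(v = v, b = b, c = cc)
}

# scaled dot-product attention as explicit loops
naive_attention <- function(Q, K, V) {
  n <- nrow(Q); dk <- ncol(Q)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    sc <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    w <- exp(sc - max(sc))
    w <- w / sum(w)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# tiny deterministic segment set
toy_segments <- function(n = 10, len = 6, labels = NULL, seed = 1) {
  set.seed(seed)
  segment_set(matrix(rnorm(n * len), n, len),
              labels %||% rep_len(1:5, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean periodogram power of rows of m in [lo, hi] Hz
band_power <- function(m, fs = 178, lo = 8, hi = 12) {
  len <- ncol(m)
  f <- (seq_len(len) - 1) * fs / len
  sel <- f >= lo & f <= hi
  mean(apply(m, 1, function(x) sum(Mod(stats::fft(x))[sel]^2 / len)))
}
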