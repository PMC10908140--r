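#' Configuration for the synthetic EEG segment generator
#'
#' The generator emulates the statistical structure of the five recording
#' conditions in single-channel scalp EEG segment data:
#' \describe{
#'   \item{class a (seizure)}{3 Hz spike-and-wave discharge at roughly 10x
#'     the background amplitude, plus heavy-tailed (Student-t) spike noise —
#'     the generalized spike-wave morphology typical of ictal recordings.}
#'   \item{class b (tumour area)}{AR(2) background with sporadic
#'     interictal-like spikes at a moderate rate.}
#'   \item{class c (healthy area)}{the same AR(2) background with a lower
#'     spike rate — deliberately confusable with class b.}
#'   \item{class d (eyes closed)}{prominent 10 Hz alpha oscillation over
#'     background.}
#'   \item{class e (eyes open)}{attenuated alpha plus broadband noise.}
#' }
#' Amplitudes are in microvolt-like units. All randomness is drawn from an
#' isolated stream derived from `seed`, so a fixed seed gives bit-identical
#' output regardless of the caller's RNG state.
#'
#' @param n_per_class segments generated per class.
#' @param segment_len samples per segment.
#' @param sampling_rate samples per second.
#' @param ar_coef AR(2) coefficients of the background process.
#' @param noise_sd innovation standard deviation of the background.
#' @param seizure_amp amplitude of the 3 Hz spike-wave (class a).
#' @param seizure_freq spike-wave frequency in Hz.
#' @param spike_mult sharp-spike multiplier on the wave amplitude (class a).
#' @param spike_rate_b,spike_rate_c sporadic spike rates (events/s) for
#'   classes b and c.
#' @param spike_amp amplitude of sporadic spikes (classes b, c).
#' @param alpha_freq alpha frequency in Hz (classes d, e).
#' @param alpha_amp_d,alpha_amp_e alpha amplitudes for classes d and e.
#' @param broadband_sd_e extra white-noise sd for class e.
#' @param seed integer RNG seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 100, segment_len = 178,
                         sampling_rate = 178,
                         ar_coef = c(1.0, -0.5), noise_sd = 10,
                         seizure_amp = 150, seizure_freq = 3,
                         spike_mult = 1.5,
                         spike_rate_b = 1.5, spike_rate_c = 0.5,
                         spike_amp = 60,
                         alpha_freq = 10, alpha_amp_d = 60, alpha_amp_e = 8,
                         broadband_sd_e = 20,
                         seed = 1L) {
  cfg <- list(n_per_class = n_per_class, segment_len = segment_len,
              sampling_rate = sampling_rate, ar_coef = ar_coef,
              noise_sd = noise_sd, seizure_amp = seizure_amp,
              seizure_freq = seizure_freq, spike_mult = spike_mult,
              spike_rate_b = spike_rate_b, spike_rate_c = spike_rate_c,
              spike_amp = spike_amp, alpha_freq = alpha_freq,
              alpha_amp_d = alpha_amp_d, alpha_amp_e = alpha_amp_e,
              broadband_sd_e = broadband_sd_e, seed = as.integer(seed))
  rates <- c(cfg$noise_sd, cfg$spike_rate_b, cfg$spike_rate_c, cfg$spike_amp,
             cfg$seizure_amp, cfg$alpha_amp_d, cfg$alpha_amp_e,
             cfg$broadband_sd_e)
  if (any(rates < 0)) stop("rates, amplitudes and sds must be >= 0")
  if (cfg$n_per_class < 0) stop("n_per_class must be >= 0")
  if (cfg$segment_len < 1) stop("segment_len must be >= 1")
  class(cfg) <- "synth_config"
  cfg
}

# Stationary AR(2) background, one segment
synth_ar2 <- function(rng, len, coef, sd) {
  innov <- rng_rnorm(rng, len + 50, sd = sd)
  x <- numeric(len + 50)
  for (t in 3:(len + 50)) {
    x[t] <- coef[1] * x[t - 1] + coef[2] * x[t - 2] + innov[t]
  }
  x[(length(x) - len + 1):length(x)]
}

# Sporadic sharp spikes: Poisson count, random positions, biphasic bump
synth_spikes <- function(rng, len, rate_per_s, amp, fs) {
  n_spk <- rng_rpois(rng, 1, rate_per_s * len / fs)
  out <- numeric(len)
  if (n_spk < 1) return(out)
  pos <- rng_sample(rng, seq_len(len), min(n_spk, len))
  width <- max(2, round(fs * 0.02))  # ~20 ms half-width
  tt <- seq_len(len)
  for (p in pos) {
    sgn <- if (rng_runif(rng, 1) < 0.5) -1 else 1
    out <- out + sgn * amp * exp(-((tt - p)^2) / (2 * width^2))
  }
  out
}

# 3 Hz spike-and-wave: slow sine wave with a sharp spike on each cycle peak
synth_spike_wave <- function(rng, len, amp, freq, mult, fs) {
  phase <- rng_runif(rng, 1, 0, 2 * pi)
  tt <- seq_len(len) / fs
  wave <- amp * sin(2 * pi * freq * tt + phase)
  period <- fs / freq
  first_peak <- ((pi / 2 - phase) %% (2 * pi)) / (2 * pi) * period
  peaks <- if (first_peak > len) numeric(0) else {
    round(seq(first_peak, len, by = period))
  }
  peaks <- peaks[peaks >= 1 & peaks <= len]
  width <- max(1.5, fs * 0.025)  # ~25 ms spike half-width
  spikes <- numeric(len)
  for (p in peaks) {
    spikes <- spikes + amp * mult * exp(-((seq_len(len) - p)^2) / (2 * width^2))
  }
  wave + spikes
}

synth_one <- function(rng, class_label, cfg) {
  len <- cfg$segment_len
  fs <- cfg$sampling_rate
  bg <- synth_ar2(rng, len, cfg$ar_coef, cfg$noise_sd)
  tt <- seq_len(len) / fs
  switch(as.character(class_label),
    "1" = bg +
      synth_spike_wave(rng, len, cfg$seizure_amp, cfg$seizure_freq,
                       cfg$spike_mult, fs) +
      cfg$seizure_amp * 0.1 * rng_rt(rng, len, df = 3),
    "2" = bg + synth_spikes(rng, len, cfg$spike_rate_b, cfg$spike_amp, fs),
    "3" = bg + synth_spikes(rng, len, cfg$spike_rate_c, cfg$spike_amp, fs),
    "4" = bg + cfg$alpha_amp_d *
      sin(2 * pi * cfg$alpha_freq * tt + rng_runif(rng, 1, 0, 2 * pi)),
    "5" = bg + cfg$alpha_amp_e *
      sin(2 * pi * cfg$alpha_freq * tt + rng_runif(rng, 1, 0, 2 * pi)) +
      rng_rnorm(rng, len, sd = cfg$broadband_sd_e)
  )
}

#' Generate a synthetic five-class EEG segment set
#'
#' Produces `n_per_class` segments for each of the five classes described in
#' [synth_config()]. Deterministic under a fixed config seed.
#'
#' @param cfg a [synth_config()].
#' @return A five-class [segment_set()].
#' @examples
#' s <- synth_generate(synth_config(n_per_class = 5, seed = 7))
#' table(s$labels)
#' @export
synth_generate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_per_class * 5L
  if (n == 0) {
    return(segment_set(matrix(0, 0, cfg$segment_len), integer(0),
                       sampling_rate = cfg$sampling_rate))
  }
  rng <- rng_stream(cfg$seed, "synth_generate")
  signals <- matrix(0, n, cfg$segment_len)
  labels <- integer(n)
  row <- 1L
  for (cl in 1:5) {
    for (i in seq_len(cfg$n_per_class)) {
      signals[row, ] <- synth_one(rng, cl, cfg)
      labels[row] <- cl
      row <- row + 1L
    }
  }
  segment_set(signals, labels, sampling_rate = cfg$sampling_rate)
}

#' Generate synthetic raw recordings (pre-segmentation)
#'
#' Same per-class signal structure as [synth_generate()] but emitted as
#' full-length recordings (4097 samples by default) suitable for
#' [segment_recordings()].
#'
#' @param cfg a [synth_config()]; `n_per_class` recordings are produced per
#'   class.
#' @param recording_len samples per recording.
#' @return A [recording_set()].
#' @export
synth_recordings <- function(cfg = synth_config(), recording_len = 4097) {
  stopifnot(inherits(cfg, "synth_config"))
  rcfg <- cfg
  rcfg$segment_len <- recording_len
  n <- cfg$n_per_class * 5L
  rng <- rng_stream(cfg$seed, "synth_recordings")
  recordings <- matrix(0, n, recording_len)
  labels <- integer(n)
  row <- 1L
  for (cl in 1:5) {
    for (i in seq_len(cfg$n_per_class)) {
      recordings[row, ] <- synth_one(rng, cl, rcfg)
      labels[row] <- cl
      row <- row + 1L
    }
  }
  recording_set(recordings, labels,
                duration_s = recording_len / cfg$sampling_rate)
}

#' Synthetic binary segments with a planted burst window
#'
#' Positive segments carry a high-amplitude 3 Hz spike-wave burst confined to
#' a known window over AR(2) background; negatives are background only. Used
#' to probe whether saliency methods localise the discriminative region.
#'
#' @param n segments per class (positives and negatives).
#' @param segment_len samples per segment.
#' @param burst_start first sample of the burst window.
#' @param burst_len window length in samples.
#' @param cfg a [synth_config()] supplying background/amplitude parameters.
#' @return A binary [segment_set()] with attribute `burst_window`
#'   (`c(start, end)`), positives labelled 1.
#' @export
synth_burst_segments <- function(n = 100, segment_len = 178,
                                 burst_start = 60, burst_len = 50,
                                 cfg = synth_config()) {
  stopifnot(burst_start >= 1, burst_start + burst_len - 1 <= segment_len)
  rng <- rng_stream(cfg$seed, "synth_burst")
  win <- burst_start:(burst_start + burst_len - 1)
  signals <- matrix(0, 2 * n, segment_len)
  labels <- integer(2 * n)
  for (i in seq_len(2 * n)) {
    x <- synth_ar2(rng, segment_len, cfg$ar_coef, cfg$noise_sd)
    if (i <= n) {
      burst <- synth_spike_wave(rng, burst_len, cfg$seizure_amp,
                                cfg$seizure_freq, cfg$spike_mult,
                                cfg$sampling_rate)
      taper <- sin(seq(0, pi, length.out = burst_len))^2
      x[win] <- x[win] + burst * taper
      labels[i] <- 1L
    }
    signals[i, ] <- x
  }
  out <- segment_set(signals, labels, label_scheme = "binary",
                     sampling_rate = cfg$sampling_rate)
  attr(out, "burst_window") <- c(burst_start, burst_start + burst_len - 1)
  out
}
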