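#' Configuration of the synthetic SSVEP generator
#'
#' Defaults emulate a 12-target joint frequency-phase coded speller:
#' fundamentals 9.25 to 14.75 Hz in 0.5 Hz steps with 0.5*pi phase steps,
#' three harmonics with 1/k amplitude decay, 8 occipital-like channels at
#' 250 Hz.
#'
#' @param n_classes number of stimulus classes.
#' @param stim_freqs fundamental frequency (Hz) per class; must be distinct.
#' @param stim_phases stimulus phase (radians) per class.
#' @param n_harmonics number of harmonics per stimulus (>= 1).
#' @param harmonic_amps amplitude per harmonic (length `n_harmonics`).
#' @param n_channels,n_trials_per_class counts.
#' @param fs sampling rate (Hz).
#' @param trial_len trial length in seconds.
#' @param snr_db task-to-background power ratio in dB; `Inf` disables noise.
#' @param mixing_seed seed for the subject-specific channel mixing.
#' @param noise_seed seed for the trial-varying background noise.
#' @param latency_jitter_sd per-trial latency jitter (seconds, standard
#'   deviation); 0 keeps the class signal phase-locked across trials.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_classes = 12L,
                         stim_freqs = seq(9.25, by = 0.5,
                                          length.out = n_classes),
                         stim_phases = seq(0, by = 0.5 * pi,
                                           length.out = n_classes) %% (2 * pi),
                         n_harmonics = 3L,
                         harmonic_amps = 1 / seq_len(n_harmonics),
                         n_channels = 8L, n_trials_per_class = 6L,
                         fs = 250, trial_len = 0.5, snr_db = 10,
                         mixing_seed = 1L, noise_seed = 2L,
                         latency_jitter_sd = 0) {
  stopifnot(length(stim_freqs) == n_classes,
            length(stim_phases) == n_classes,
            n_harmonics >= 1L,
            length(harmonic_amps) == n_harmonics)
  if (anyDuplicated(stim_freqs)) stop("stim_freqs must be distinct")
  if (max(stim_freqs) * n_harmonics >= fs / 2)
    stop(sprintf(
      "highest harmonic (%g Hz) aliases: must be below fs/2 = %g Hz",
      max(stim_freqs) * n_harmonics, fs / 2))
  structure(as.list(environment()), class = "synth_config")
}

#' 1/f (pink) background noise
#'
#' Spectrally shaped Gaussian noise with power spectral density proportional
#' to 1/f (amplitude ~ f^{-1/2}), zero mean and unit variance. Generated by
#' shaping white noise in the frequency domain with a conjugate-symmetric
#' 1/sqrt(f) envelope (DC removed), then standardized.
#'
#' @param n_samples length of the signal (>= 2).
#' @param seed optional integer seed; when given the draw is deterministic
#'   and the caller's RNG state is untouched.
#' @return numeric vector of length `n_samples`.
#' @export
pink_noise <- function(n_samples, seed = NULL) {
  stopifnot(n_samples >= 2)
  gen <- function() {
    w <- stats::rnorm(n_samples)
    sp <- stats::fft(w)
    k <- seq_len(n_samples) - 1
    f <- pmin(k, n_samples - k)          # symmetric bin frequency
    env <- ifelse(f == 0, 0, 1 / sqrt(f))
    x <- Re(stats::fft(sp * env, inverse = TRUE)) / n_samples
    (x - mean(x)) / stats::sd(x)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Noise-free class signal matrix [n_classes x n_samples]:
# sum of harmonics k*f with phase k*phi and amplitude amps[k].
synth_class_signals <- function(cfg, n_s = NULL) {
  if (is.null(n_s)) n_s <- floor(cfg$trial_len * cfg$fs)
  t <- (seq_len(n_s) - 1) / cfg$fs
  s <- matrix(0, cfg$n_classes, n_s)
  for (m in seq_len(cfg$n_classes)) {
    for (k in seq_len(cfg$n_harmonics)) {
      s[m, ] <- s[m, ] + cfg$harmonic_amps[k] *
        sin(2 * pi * k * cfg$stim_freqs[m] * t + k * cfg$stim_phases[m])
    }
  }
  s
}

#' Generate a synthetic SSVEP dataset
#'
#' Every trial is the sum of (i) the class signal (fundamental plus
#' harmonics, identical across trials of a class) projected into channel
#' space by a fixed subject-specific spatial pattern, (ii) 1/f background
#' noise generated independently per channel and spatially smeared by a
#' random full-rank mixing matrix (so the background is spatially correlated
#' while the task component lives in a low-rank subspace), and (iii) white
#' sensor noise. The combined noise is scaled so that the trial-wise
#' task-to-background power ratio equals `snr_db`. Deterministic under
#' `mixing_seed` / `noise_seed`.
#'
#' @param cfg a [synth_config()].
#' @return an `epoched_eeg`; the noise-free per-class channel signals and
#'   spatial patterns are attached as `attr(,"ground_truth")`.
#' @export
synth_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n_s <- floor(cfg$trial_len * cfg$fs)
  n_c <- cfg$n_channels
  n_k <- cfg$n_classes
  n_t <- cfg$n_trials_per_class
  src <- synth_class_signals(cfg, n_s)

  mix <- with_seed(cfg$mixing_seed, {
    patterns <- matrix(stats::rnorm(n_c * n_k), n_c, n_k)
    patterns <- sweep(patterns, 2, sqrt(colSums(patterns^2)), "/")
    noise_mix <- matrix(stats::rnorm(n_c * n_c), n_c, n_c)
    noise_mix <- noise_mix / sqrt(n_c)
    list(patterns = patterns, noise_mix = noise_mix)
  })

  total <- n_k * n_t
  dat <- array(0, dim = c(total, n_c, n_s))
  labels <- integer(total)
  sensor_frac <- 0.1                      # share of noise power that is white
  with_seed(cfg$noise_seed, {
    i <- 0L
    for (m in seq_len(n_k)) {
      clean <- mix$patterns[, m, drop = FALSE] %*% src[m, , drop = FALSE]
      p_sig <- mean(clean^2)
      for (h in seq_len(n_t)) {
        i <- i + 1L
        labels[i] <- m - 1L
        sig <- clean
        if (cfg$latency_jitter_sd > 0) {
          shift <- round(stats::rnorm(1, 0, cfg$latency_jitter_sd) * cfg$fs)
          tt <- (seq_len(n_s) - 1 + shift) / cfg$fs
          s_m <- numeric(n_s)
          for (k in seq_len(cfg$n_harmonics))
            s_m <- s_m + cfg$harmonic_amps[k] *
              sin(2 * pi * k * cfg$stim_freqs[m] * tt + k * cfg$stim_phases[m])
          sig <- mix$patterns[, m, drop = FALSE] %*% matrix(s_m, 1)
        }
        if (is.finite(cfg$snr_db)) {
          pink <- t(vapply(seq_len(n_c), function(j) pink_noise(n_s),
                           numeric(n_s)))
          bg <- mix$noise_mix %*% pink
          white <- matrix(stats::rnorm(n_c * n_s), n_c, n_s)
          bg <- sqrt(1 - sensor_frac) * bg / sqrt(mean(bg^2)) +
                sqrt(sensor_frac) * white / sqrt(mean(white^2))
          p_target <- p_sig / 10^(cfg$snr_db / 10)
          noise <- bg * sqrt(p_target / mean(bg^2))
          dat[i, , ] <- sig + noise
        } else {
          dat[i, , ] <- sig
        }
      }
    }
  })
  e <- epoched_eeg(dat, labels, cfg$fs,
                   channel_names = paste0("syn", seq_len(n_c)),
                   subject_id = "synthetic", n_classes = n_k)
  attr(e, "ground_truth") <- list(class_signals = src,
                                  patterns = mix$patterns,
                                  noise_mix = mix$noise_mix)
  e
}
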