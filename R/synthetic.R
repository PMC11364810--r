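# Evaluate `expr` under a private RNG stream, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration for the synthetic motor-imagery generator
#'
#' Describes a class-conditional band-power modulation experiment: every trial
#' is per-channel 1/f background noise; channels listed in
#' `class_channel_map` additionally carry a band-limited oscillation (mu or
#' beta band by default), and on the channels mapped to a trial's own class
#' the oscillation power is scaled by `(1 + effect)`. With `effect = 0` all
#' classes are exchangeable in distribution.
#'
#' @param n_per_class trials generated per class.
#' @param C number of channels.
#' @param T_samples samples per trial.
#' @param fs sampling rate in Hz.
#' @param n_classes number of classes `N`.
#' @param class_channel_map list of length `N`; element `c` holds the 1-based
#'   channel indices carrying class `c`'s discriminative modulation. Defaults
#'   to channel `c` for class `c`.
#' @param band numeric `(low, high)` oscillation band in Hz; default mu
#'   (8-13 Hz). May also be a list of one band per class.
#' @param effect fractional band-power modulation depth (>= 0); the mapped
#'   channels of a class's own trials carry `(1 + effect)` times the baseline
#'   oscillation power.
#' @param noise_exponent spectral slope of the 1/f^a background (default 1).
#' @param osc_sd baseline oscillation amplitude (standard deviation, default 1).
#' @param noise_sd background noise standard deviation (default 1).
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 50L, C = 3L, T_samples = 1000L,
                         fs = 250, n_classes = 2L, class_channel_map = NULL,
                         band = c(8, 13), effect = 1, noise_exponent = 1,
                         osc_sd = 1, noise_sd = 1, seed = 1L) {
  if (is.null(class_channel_map)) {
    class_channel_map <- lapply(seq_len(n_classes), function(c) ((c - 1L) %% C) + 1L)
  }
  if (!is.list(band)) band <- rep(list(band), n_classes)
  cfg <- structure(
    list(n_per_class = as.integer(n_per_class), C = as.integer(C),
         T_samples = as.integer(T_samples), fs = as.numeric(fs),
         n_classes = as.integer(n_classes), class_channel_map = class_channel_map,
         band = band, effect = as.numeric(effect),
         noise_exponent = as.numeric(noise_exponent),
         osc_sd = as.numeric(osc_sd), noise_sd = as.numeric(noise_sd),
         seed = as.integer(seed)),
    class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_per_class < 1L) stop("synth_config: n_per_class must be >= 1")
  if (cfg$effect < 0) stop("synth_config: effect must be >= 0")
  if (length(cfg$class_channel_map) != cfg$n_classes) {
    stop("synth_config: class_channel_map must have one entry per class")
  }
  for (chans in cfg$class_channel_map) {
    if (length(chans) < 1L || any(chans < 1L) || any(chans > cfg$C)) {
      stop("synth_config: mapped channel index outside 1..C")
    }
  }
  for (b in cfg$band) {
    if (length(b) != 2L || b[1] <= 0 || b[2] <= b[1] || b[2] > cfg$fs / 2) {
      stop("synth_config: band must be (low, high) inside (0, fs/2]")
    }
  }
  invisible(cfg)
}

# Power-law (1/f^a) noise via spectral shaping, unit variance.
pink_noise <- function(T_samples, exponent) {
  x <- stats::rnorm(T_samples)
  if (exponent == 0) return(x)
  X <- stats::fft(x)
  # frequency index of each FFT bin (0, 1, ..., T/2, ..., 1); DC left alone
  k <- c(0, seq_len(T_samples - 1))
  k <- pmin(k, T_samples - k)
  g <- c(0, k[-1]^(-exponent / 2))
  y <- Re(stats::fft(X * g, inverse = TRUE)) / T_samples
  s <- stats::sd(y)
  if (s == 0) stop("degenerate noise realization")
  y / s
}

# Band-limited Gaussian noise: white noise brick-walled to [low, high] Hz,
# scaled to unit expected variance analytically (kept-bin fraction).
band_noise <- function(T_samples, fs, band) {
  x <- stats::rnorm(T_samples)
  X <- stats::fft(x)
  freq <- (seq_len(T_samples) - 1) * fs / T_samples
  freq <- pmin(freq, fs - freq)             # mirror to two-sided
  keep <- freq >= band[1] & freq <= band[2]
  if (!any(keep)) stop("band contains no FFT bins at this T and fs")
  y <- Re(stats::fft(X * keep, inverse = TRUE)) / T_samples
  y / sqrt(mean(keep))
}

#' Generate class-conditional synthetic motor-imagery trials
#'
#' Emits `n_per_class * n_classes` trials of 1/f background noise; each
#' class's mapped channels carry a narrow-band oscillation (band-filtered
#' Gaussian noise, not a sinusoid) whose variance is `(1 + effect)` times the
#' baseline when the trial belongs to that class. Classes are balanced and
#' interleaved; output is bit-reproducible for a fixed seed and leaves the
#' caller's RNG state untouched.
#'
#' @param cfg a [synth_config()].
#' @param subject_id,session_tag provenance fields for the returned set.
#' @return a `trial_set` of dimension
#'   `(n_per_class * n_classes) x C x T_samples`.
#' @export
generate_mi_trials <- function(cfg, subject_id = "sim01", session_tag = "train") {
  validate_synth_config(cfg)
  n_tot <- cfg$n_per_class * cfg$n_classes
  with_local_seed(cfg$seed, {
    data <- array(0, c(n_tot, cfg$C, cfg$T_samples))
    labels <- integer(n_tot)
    # which classes modulate each channel (a channel may serve several)
    for (i in seq_len(n_tot)) {
      cls <- (i - 1L) %% cfg$n_classes          # interleaved, balanced
      labels[i] <- cls
      for (ch in seq_len(cfg$C)) {
        sig <- cfg$noise_sd * pink_noise(cfg$T_samples, cfg$noise_exponent)
        for (c2 in seq_len(cfg$n_classes)) {
          if (ch %in% cfg$class_channel_map[[c2]]) {
            amp <- cfg$osc_sd
            if (cls == c2 - 1L) amp <- amp * sqrt(1 + cfg$effect)
            sig <- sig + amp * band_noise(cfg$T_samples, cfg$fs, cfg$band[[c2]])
          }
        }
        data[i, ch, ] <- sig
      }
    }
    trial_set(data, labels, cfg$fs, NULL, cfg$n_classes, subject_id, session_tag)
  })
}

#' Generate one synthetic subject per seed
#'
#' Convenience wrapper for the cross-subject protocols: produces a list of
#' independent `trial_set`s drawn from the same configuration, one per seed,
#' tagged `"sub01"`, `"sub02"`, ...
#'
#' @param cfg a [synth_config()]; its `seed` field is ignored.
#' @param seeds integer vector, one seed per subject.
#' @return list of `trial_set`s.
#' @export
generate_mi_subjects <- function(cfg, seeds) {
  lapply(seq_along(seeds), function(i) {
    cfg$seed <- as.integer(seeds[i])
    generate_mi_trials(cfg, subject_id = sprintf("sub%02d", i))
  })
}
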