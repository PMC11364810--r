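#' Per-trial Z-score standardization
#'
#' Standardizes one EEG trial with its scalar mean and standard deviation
#' taken over all `C x T` entries: `(X - mu) / delta`. The population
#' standard deviation (divide by `C*T`) is used. Idempotent up to numerical
#' tolerance.
#'
#' @param trial numeric `C x T` matrix.
#' @return the standardized `C x T` matrix (mean 0, population SD 1).
#' @export
zscore_trial <- function(trial) {
  if (!is.matrix(trial) || !is.numeric(trial)) stop("trial must be a numeric matrix")
  mu <- mean(trial)
  delta <- sqrt(mean((trial - mu)^2))
  if (delta == 0) stop("degenerate trial: standard deviation is zero")
  (trial - mu) / delta
}

#' Standardize every trial of a trial_set
#'
#' Applies [zscore_trial()] independently to each trial. This is the only
#' preprocessing the pipeline performs (no filtering, no artifact removal)
#' and precedes augmentation and the model input.
#'
#' @param ts a `trial_set`.
#' @return a `trial_set` with standardized trials.
#' @export
zscore_trialset <- function(ts) {
  validate_trial_set(ts)
  out <- ts
  for (i in seq_len(n_trials(ts))) {
    out$data[i, , ] <- zscore_trial(array(ts$data[i, , ],
                                          dim(ts$data)[2:3]))
  }
  out
}

#' Segmentation-and-recombination augmentation settings
#'
#' @param K number of equal, non-overlapping temporal segments each trial is
#'   split into; the trial length must be divisible by `K`. Default 8, which
#'   cuts the benchmarks' 1000-sample trials into 125-sample segments.
#' @param multiplier artificial trials generated per original trial
#'   (default 1, i.e. the training set doubles); 0 disables augmentation.
#' @param seed RNG seed governing the segment-source draws.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(K = 8L, multiplier = 1L, seed = 1L) {
  K <- as.integer(K); multiplier <- as.integer(multiplier)
  if (K < 1L) stop("augment_config: K must be >= 1")
  if (multiplier < 0L) stop("augment_config: multiplier must be >= 0")
  structure(list(K = K, multiplier = multiplier, seed = as.integer(seed)),
            class = "augment_config")
}

#' Segmentation-and-recombination (S&R) augmentation
#'
#' Splits each trial into `K` contiguous equal segments and builds artificial
#' trials by concatenating, in original temporal order, segment `k` of a
#' uniformly chosen trial of the *same class* for each position `k`. Returns
#' only the artificial trials: `multiplier` per original trial, so class
#' proportions mirror the input. Segments are copied verbatim; a fixed seed
#' reproduces the draws exactly.
#'
#' @param ts a `trial_set` (standardize first; augmentation is intended for
#'   the training split only, after the train/validation split).
#' @param cfg an [augment_config()].
#' @return a `trial_set` of `multiplier * n_trials(ts)` artificial trials
#'   (0 trials if `multiplier = 0`).
#' @export
segment_recombine <- function(ts, cfg) {
  validate_trial_set(ts)
  stopifnot(inherits(cfg, "augment_config"))
  d <- dim(ts$data); T_len <- d[3L]
  if (T_len %% cfg$K != 0L) {
    stop("segment_recombine: trial length ", T_len, " not divisible by K = ", cfg$K)
  }
  counts <- table(factor(ts$labels, levels = 0:(ts$n_classes - 1L)))
  if (any(counts == 0L)) {
    stop("segment_recombine: class ", names(counts)[which(counts == 0L)[1L]],
         " has no trials")
  }
  n_art <- cfg$multiplier * n_trials(ts)
  out <- array(0, c(n_art, d[2L], T_len))
  labels <- integer(n_art)
  seg_len <- T_len %/% cfg$K
  by_class <- split(seq_len(n_trials(ts)), ts$labels)
  with_local_seed(cfg$seed, {
    j <- 0L
    for (i in seq_len(n_trials(ts))) {
      cls <- ts$labels[i]
      pool <- by_class[[as.character(cls)]]
      for (m in seq_len(cfg$multiplier)) {
        j <- j + 1L
        labels[j] <- cls
        src <- pool[sample.int(length(pool), cfg$K, replace = TRUE)]
        for (k in seq_len(cfg$K)) {
          span <- ((k - 1L) * seg_len + 1L):(k * seg_len)
          out[j, , span] <- ts$data[src[k], , span]
        }
      }
    }
  })
  ts_out <- ts
  ts_out$data <- out
  ts_out$labels <- labels
  ts_out$prediction_only <- n_art == 0L
  validate_trial_set(ts_out)
  ts_out
}

#' Augment a training set in place
#'
#' Standard wiring used by the training protocols: keeps the originals and
#' appends the S&R artificial trials (no-op when `multiplier = 0`).
#'
#' @param ts training `trial_set`.
#' @param cfg an [augment_config()].
#' @return `ts` plus artificial trials.
#' @export
augment_training_set <- function(ts, cfg) {
  if (cfg$multiplier == 0L) return(ts)
  art <- segment_recombine(ts, cfg)
  bind_trials(list(ts, art), subject_id = ts$subject_id)
}
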