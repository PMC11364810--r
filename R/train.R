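# Optimization and evaluation protocols: Adam with validation-based model
# selection, subject-specific training, and leave-one-subject-out (LOSO)
# cross-validation.

#' Training hyperparameters
#'
#' Defaults follow the benchmark protocols: Adam with learning rate 0.001 and
#' betas (0.5, 0.999), 30% of the initial training set reserved for
#' validation, batch size 288 and 1000 epochs for subject-specific runs, or
#' batch size 512 and 600 epochs for the cross-subject (LOSO) profile. When
#' the batch size exceeds the post-split training size a single full batch is
#' used. The model snapshot with minimum validation loss is returned; no
#' early stopping.
#'
#' @param profile `"subject_specific"` or `"cross_subject"`; sets the batch
#'   size/epoch defaults and the convolutional dropout profile.
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param batch_size mini-batch size (capped at the training-set size).
#' @param epochs training epochs; all are run.
#' @param val_fraction validation fraction in (0, 1).
#' @param seed master seed for split/augmentation/init/shuffling streams.
#' @param augment an [augment_config()]; `multiplier = 0` disables S&R.
#' @return an object of class `train_config`.
#' @export
train_config <- function(profile = c("subject_specific", "cross_subject"),
                         learning_rate = 0.001, beta1 = 0.5, beta2 = 0.999,
                         batch_size = NULL, epochs = NULL, val_fraction = 0.30,
                         seed = 1L, augment = augment_config()) {
  profile <- match.arg(profile)
  if (is.null(batch_size)) batch_size <- if (profile == "subject_specific") 288L else 512L
  if (is.null(epochs)) epochs <- if (profile == "subject_specific") 1000L else 600L
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("train_config: val_fraction must lie strictly between 0 and 1")
  }
  if (epochs < 1L) stop("train_config: epochs must be >= 1")
  if (batch_size < 1L) stop("train_config: batch_size must be >= 1")
  structure(list(profile = profile, learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), val_fraction = val_fraction,
                 seed = as.integer(seed), augment = augment),
            class = "train_config")
}

# deterministic per-task seed fan-out from a master seed
derive_seed <- function(seed, stream, i = 1L) {
  as.integer((as.double(seed) * 48271 + stream * 9973 + i * 101) %% 2147483647)
}

#' Stratified train/validation split
#'
#' Randomly reserves `val_fraction` of each class for validation (rounded to
#' the nearest trial, at least one per class on each side). Deterministic for
#' a fixed seed; the two parts are disjoint and their union is the input.
#'
#' @param ts a `trial_set` with at least 2 trials per class.
#' @param val_fraction fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with `train` and `val` trial_sets.
#' @export
split_train_val <- function(ts, val_fraction, seed = 1L) {
  validate_trial_set(ts)
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("split error: val_fraction must lie strictly between 0 and 1")
  }
  by_class <- split(seq_len(n_trials(ts)), ts$labels)
  if (any(vapply(by_class, length, integer(1)) < 2L)) {
    stop("split error: every class needs at least 2 trials")
  }
  # allocate round(fraction * total) validation trials over classes by
  # largest remainder, so each class is within one trial of the fraction
  sizes <- vapply(by_class, length, integer(1))
  exact <- val_fraction * sizes
  n_val_c <- pmax(1L, pmin(sizes - 1L, floor(exact)))
  target <- max(length(sizes), min(sum(sizes) - length(sizes),
                                   round(val_fraction * sum(sizes))))
  short <- target - sum(n_val_c)
  if (short > 0) {
    ord <- order(exact - floor(exact), decreasing = TRUE)
    for (j in ord) {
      if (short == 0L) break
      if (n_val_c[j] < sizes[j] - 1L) { n_val_c[j] <- n_val_c[j] + 1L; short <- short - 1L }
    }
  }
  with_local_seed(seed, {
    val_idx <- integer(0)
    for (k in seq_along(by_class)) {
      val_idx <- c(val_idx, sample(by_class[[k]], n_val_c[k]))
    }
    val_idx <- sort(val_idx)
    train_idx <- setdiff(seq_len(n_trials(ts)), val_idx)
    list(train = subset_trials(ts, train_idx, prediction_only = FALSE),
         val = subset_trials(ts, val_idx, prediction_only = FALSE))
  })
}

#' Multi-class cross-entropy loss
#'
#' `-(1/M) * sum_i sum_j y_ij log(yhat_ij)`. Probabilities are clamped at
#' 1e-12 before the log so a zero probability at a true label yields a large
#' finite loss rather than infinity.
#'
#' @param probs `M x N` matrix of predicted class probabilities (rows sum
#'   to 1).
#' @param labels either an `M x N` one-hot matrix or a length-`M` vector of
#'   0-based class indices.
#' @return scalar mean loss.
#' @export
cross_entropy <- function(probs, labels) {
  probs <- rbind(probs)
  M <- nrow(probs)
  if (is.matrix(labels)) {
    Y <- labels
  } else {
    Y <- matrix(0, M, ncol(probs))
    Y[cbind(seq_len(M), as.integer(labels) + 1L)] <- 1
  }
  stopifnot(identical(dim(Y), dim(probs)))
  -sum(Y * log(pmax(probs, 1e-12))) / M
}

# ---- parameter flattening for the optimizer --------------------------------

flatten_params <- function(p) unlist(p, recursive = TRUE, use.names = FALSE)

# reorder a gradient list to the exact shape/order of the parameter skeleton
align_to_skeleton <- function(g, skeleton) {
  if (!is.list(skeleton)) return(g)
  nm <- names(skeleton)
  if (is.null(nm)) {
    return(lapply(seq_along(skeleton),
                  function(i) align_to_skeleton(g[[i]], skeleton[[i]])))
  }
  out <- stats::setNames(vector("list", length(nm)), nm)
  for (k in nm) {
    if (is.null(g[[k]])) stop("missing gradient for parameter `", k, "`")
    out[[k]] <- align_to_skeleton(g[[k]], skeleton[[k]])
  }
  out
}

flatten_grads <- function(g, skeleton) {
  flatten_params(align_to_skeleton(g, skeleton))
}

unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  fill(skeleton)
}

#' Fit a model with Adam and validation-based selection
#'
#' Standard training loop: shuffled mini-batches, Adam updates
#' (`epsilon = 1e-8`, no weight decay), batch-norm running statistics updated
#' in training mode. After every epoch the model is scored on the validation
#' set in evaluation mode; the parameter snapshot with the minimum validation
#' loss (earliest epoch on ties) is returned. Fully reproducible for a fixed
#' `cfg$seed`.
#'
#' Inputs are expected to be standardized already, and any augmentation
#' applied to `train` only — the protocol runners take care of both.
#'
#' @param model a freshly built (or warm) `ctnet_model`.
#' @param train,val standardized `trial_set`s.
#' @param cfg a [train_config()].
#' @return list with `model` (best snapshot) and `history` (data frame of
#'   per-epoch `train_loss`, `val_loss`, `val_acc`, plus attribute-free column
#'   `epoch`; `selected_epoch` gives the chosen row).
#' @export
fit <- function(model, train, val, cfg) {
  validate_trial_set(train); validate_trial_set(val)
  if (n_trials(train) == 0L || n_trials(val) == 0L) {
    stop("fit: empty training or validation set")
  }
  n_tr <- n_trials(train)
  bs <- min(cfg$batch_size, n_tr)
  skeleton <- model$params
  theta <- flatten_params(model$params)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  eps <- 1e-8; step <- 0L
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                     val_loss = NA_real_, val_acc = NA_real_)
  best <- list(loss = Inf, params = model$params, buffers = model$buffers,
               epoch = NA_integer_)
  with_local_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample.int(n_tr)
      batch_losses <- c()
      for (start in seq(1L, n_tr, by = bs)) {
        take <- idx[start:min(n_tr, start + bs - 1L)]
        Xb <- train$data[take, , , drop = FALSE]
        yb <- train$labels[take]
        fw <- ctnet_full_forward(model, Xb, training = TRUE)
        model$buffers <- fw$buffers
        probs <- softmax_rows(fw$logits)
        batch_losses <- c(batch_losses, cross_entropy(probs, yb))
        Y <- matrix(0, length(take), model$config$N)
        Y[cbind(seq_along(take), yb + 1L)] <- 1
        dlogits <- (probs - Y) / length(take)
        grads <- ctnet_full_backward(model, dlogits, fw$cache)
        gvec <- flatten_grads(grads, skeleton)
        step <- step + 1L
        m <- cfg$beta1 * m + (1 - cfg$beta1) * gvec
        v <- cfg$beta2 * v + (1 - cfg$beta2) * gvec^2
        mhat <- m / (1 - cfg$beta1^step)
        vhat <- v / (1 - cfg$beta2^step)
        theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        model$params <- unflatten_params(theta, skeleton)
      }
      pv <- model_forward(model, val)$probs
      val_loss <- cross_entropy(pv, val$labels)
      val_acc <- mean(max.col(pv, ties.method = "first") - 1L == val$labels)
      hist$train_loss[ep] <- mean(batch_losses)
      hist$val_loss[ep] <- val_loss
      hist$val_acc[ep] <- val_acc
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = model$params,
                     buffers = model$buffers, epoch = ep)
      }
    }
  })
  model$params <- best$params
  model$buffers <- best$buffers
  attr(hist, "selected_epoch") <- best$epoch
  list(model = model, history = hist, selected_epoch = best$epoch)
}

#' Evaluate a model on a test trial_set
#'
#' @param model a trained `ctnet_model`.
#' @param test a standardized `trial_set`.
#' @param subject_id label for the result; defaults to the set's subject.
#' @return a `subject_result`: confusion matrix, accuracy, kappa.
#' @export
evaluate_model <- function(model, test, subject_id = NULL) {
  validate_trial_set(test)
  if (n_trials(test) == 0L) stop("evaluate_model: empty test set")
  pred <- predict_labels(model, test)
  cm <- confusion_matrix(test$labels, pred, test$n_classes)
  subject_result(subject_id %||% test$subject_id, cm)
}

#' Content fingerprints of every trial in a set
#'
#' A cheap content signature (sums of the values, their squares, and the
#' first channel) per trial, used to audit the protocols for train/test
#' leakage: with continuous-valued data, two distinct trials collide with
#' probability zero.
#'
#' @param ts a `trial_set`.
#' @return character vector, one fingerprint per trial.
#' @export
trial_fingerprints <- function(ts) {
  vapply(seq_len(n_trials(ts)), function(i) {
    x <- ts$data[i, , ]
    paste(format(c(sum(x), sum(x * x), sum(ts$data[i, 1, ])), digits = 15),
          collapse = "|")
  }, character(1))
}

# shared per-subject pipeline: standardize, split, augment, fit, evaluate
fit_and_score <- function(train_ts, test_ts, model_cfg, train_cfg, run_seed) {
  train_std <- zscore_trialset(train_ts)
  test_std <- zscore_trialset(test_ts)
  sp <- split_train_val(train_std, train_cfg$val_fraction,
                        seed = derive_seed(run_seed, 1L))
  aug <- train_cfg$augment
  aug$seed <- derive_seed(run_seed, 2L)
  tr <- augment_training_set(sp$train, aug)
  model <- build_model(model_cfg, seed = derive_seed(run_seed, 3L))
  fit_cfg <- train_cfg
  fit_cfg$seed <- derive_seed(run_seed, 4L)
  fitted <- fit(model, tr, sp$val, fit_cfg)
  res <- evaluate_model(fitted$model, test_std, subject_id = test_ts$subject_id)
  res$history <- fitted$history
  res$selected_epoch <- fitted$selected_epoch
  # signatures of everything that influenced training/model selection,
  # so callers can audit that no test trial leaked in
  res$train_fingerprints <- c(trial_fingerprints(tr), trial_fingerprints(sp$val))
  res
}

#' Subject-specific protocol
#'
#' For each subject independently: standardize, split the subject's training
#' session into train/validation (stratified), apply S&R augmentation to the
#' training part only, fit with validation-based selection, and score on the
#' subject's own test session.
#'
#' @param train_sets,test_sets lists of `trial_set`s, one pair per subject,
#'   in matching order.
#' @param model_cfg a [model_config()]; defaults to the benchmark
#'   architecture for the data's geometry with the subject-specific dropout
#'   profile.
#' @param train_cfg a [train_config()].
#' @return list of `subject_result`s.
#' @export
run_subject_specific <- function(train_sets, test_sets, model_cfg = NULL,
                                 train_cfg = train_config("subject_specific")) {
  if (length(train_sets) != length(test_sets) || length(train_sets) == 0L) {
    stop("run_subject_specific: need matching non-empty train/test subject lists")
  }
  ids_tr <- vapply(train_sets, `[[`, "", "subject_id")
  ids_te <- vapply(test_sets, `[[`, "", "subject_id")
  if (!identical(ids_tr, ids_te)) {
    stop("run_subject_specific: subject lists do not match: ",
         paste(ids_tr, collapse = ","), " vs ", paste(ids_te, collapse = ","))
  }
  ref <- train_sets[[1L]]
  if (is.null(model_cfg)) {
    model_cfg <- model_config(dim(ref$data)[2L], dim(ref$data)[3L],
                              ref$n_classes, dropout_profile = "subject_specific")
  }
  lapply(seq_along(train_sets), function(i) {
    fit_and_score(train_sets[[i]], test_sets[[i]], model_cfg, train_cfg,
                  run_seed = derive_seed(train_cfg$seed, 10L, i))
  })
}

#' Leave-one-subject-out (LOSO) protocol
#'
#' For each held-out subject: pool every other subject's trials as the
#' training set, reserve the validation fraction (stratified), augment the
#' training part, fit with the cross-subject dropout profile (`p1 = 0.25`),
#' and score on the held-out subject. The held-out trials never enter the
#' training pool.
#'
#' @param sets list of >= 2 `trial_set`s, one per subject.
#' @param model_cfg a [model_config()]; defaults to the benchmark
#'   architecture with the cross-subject dropout profile.
#' @param train_cfg a [train_config()] (use `profile = "cross_subject"`).
#' @return list of `subject_result`s, one per held-out subject.
#' @export
run_loso <- function(sets, model_cfg = NULL,
                     train_cfg = train_config("cross_subject")) {
  if (length(sets) < 2L) stop("run_loso: need at least 2 subjects")
  for (s in sets) {
    validate_trial_set(s)
    if (n_trials(s) == 0L) stop("run_loso: subject ", s$subject_id, " is empty")
  }
  ref <- sets[[1L]]
  if (is.null(model_cfg)) {
    model_cfg <- model_config(dim(ref$data)[2L], dim(ref$data)[3L],
                              ref$n_classes, dropout_profile = "cross_subject")
  }
  lapply(seq_along(sets), function(i) {
    pool <- bind_trials(sets[-i], subject_id = paste0("all-but-", sets[[i]]$subject_id))
    fit_and_score(pool, sets[[i]], model_cfg, train_cfg,
                  run_seed = derive_seed(train_cfg$seed, 20L, i))
  })
}
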