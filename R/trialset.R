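#' Labelled collection of EEG trials
#'
#' A `trial_set` bundles a numeric trial tensor (trials x channels x samples)
#' with 0-based integer class labels, the sampling rate, channel names and
#' provenance metadata. It is the common currency of the whole package: the
#' synthetic generator emits it, the GDF loader produces it, and the
#' preprocessing, training and evaluation stages consume it.
#'
#' @param data numeric array of dimension `trials x channels x samples`.
#' @param labels integer vector, one 0-based class index per trial.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names character vector naming the channels; defaults to
#'   `"ch1" ... "chC"`.
#' @param n_classes number of classes `N`; labels must lie in `[0, N-1]`.
#'   Defaults to `max(labels) + 1`.
#' @param subject_id free-form subject identifier.
#' @param session_tag `"train"` or `"test"` provenance tag.
#' @param prediction_only logical; if `TRUE` the set may miss some classes
#'   (e.g. an unlabeled evaluation split) and the every-class-present check is
#'   skipped.
#'
#' @return an object of class `trial_set`.
#' @export
trial_set <- function(data, labels, fs, channel_names = NULL,
                      n_classes = NULL, subject_id = "S01",
                      session_tag = c("train", "test"),
                      prediction_only = FALSE) {
  session_tag <- match.arg(session_tag)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (trials x channels x samples)")
  }
  storage.mode(data) <- "double"
  labels <- as.integer(labels)
  if (is.null(n_classes)) {
    if (length(labels) == 0L) stop("`n_classes` required for an empty trial_set")
    n_classes <- max(labels) + 1L
  }
  n_classes <- as.integer(n_classes)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dim(data)[2L]))
  ts <- structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         channel_names = as.character(channel_names), n_classes = n_classes,
         subject_id = as.character(subject_id), session_tag = session_tag,
         prediction_only = isTRUE(prediction_only)),
    class = "trial_set")
  validate_trial_set(ts)
  ts
}

#' Validate the trial_set invariants
#'
#' Checks the dimensional contract (first data dimension equals the number of
#' labels), the label range `[0, N-1]`, presence of every class (unless the
#' set is flagged prediction-only), a positive sampling rate, and channel-name
#' consistency. Called by all constructors; exported because the loaders use
#' it on untrusted input.
#'
#' @param ts a `trial_set`.
#' @return `ts`, invisibly, if valid; otherwise an error naming the offending
#'   field.
#' @export
validate_trial_set <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  d <- dim(ts$data)
  if (d[1L] != length(ts$labels)) {
    stop("trial_set field `labels`: length ", length(ts$labels),
         " does not match ", d[1L], " trials")
  }
  if (ts$fs <= 0) stop("trial_set field `fs`: must be > 0")
  if (d[2L] < 1L || d[3L] < 1L) {
    stop("trial_set field `data`: needs at least 1 channel and 1 sample")
  }
  if (length(ts$channel_names) != d[2L]) {
    stop("trial_set field `channel_names`: length ", length(ts$channel_names),
         " does not match ", d[2L], " channels")
  }
  if (ts$n_classes < 1L) stop("trial_set field `n_classes`: must be >= 1")
  if (length(ts$labels) > 0L) {
    if (anyNA(ts$labels) || min(ts$labels) < 0L || max(ts$labels) >= ts$n_classes) {
      stop("trial_set field `labels`: values must lie in [0, ", ts$n_classes - 1L, "]")
    }
    if (!ts$prediction_only &&
        length(unique(ts$labels)) < ts$n_classes) {
      stop("trial_set field `labels`: not every class in [0, ",
           ts$n_classes - 1L, "] is present (set prediction_only = TRUE to allow)")
    }
  }
  invisible(ts)
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  classes: %d | subject: %s | session: %s\n",
              x$n_classes, x$subject_id, x$session_tag))
  if (length(x$labels)) {
    tab <- table(factor(x$labels, levels = 0:(x$n_classes - 1L)))
    cat("  per-class counts:", paste(as.integer(tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of trials in a trial_set
#' @param ts a `trial_set`.
#' @return integer trial count.
#' @export
n_trials <- function(ts) dim(ts$data)[1L]

#' Subset a trial_set by trial index
#' @param ts a `trial_set`.
#' @param idx integer vector of trial indices (1-based).
#' @param prediction_only propagate or set the prediction-only flag; a subset
#'   may drop classes, so this defaults to `TRUE`.
#' @return a `trial_set` with the selected trials.
#' @export
subset_trials <- function(ts, idx, prediction_only = TRUE) {
  trial_set(ts$data[idx, , , drop = FALSE], ts$labels[idx], ts$fs,
            ts$channel_names, ts$n_classes, ts$subject_id, ts$session_tag,
            prediction_only = prediction_only)
}

#' Concatenate trial_sets along the trial dimension
#' @param ... `trial_set` objects with identical geometry, fs and class count.
#' @param subject_id subject tag for the pooled set.
#' @return a pooled `trial_set`.
#' @export
bind_trials <- function(..., subject_id = "pooled") {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !inherits(sets[[1L]], "trial_set")) {
    sets <- sets[[1L]]
  }
  stopifnot(length(sets) >= 1L)
  ref <- sets[[1L]]
  for (s in sets) {
    stopifnot(inherits(s, "trial_set"),
              identical(dim(s$data)[2:3], dim(ref$data)[2:3]),
              s$fs == ref$fs, s$n_classes == ref$n_classes)
  }
  dat <- do.call(abind3, lapply(sets, `[[`, "data"))
  labs <- unlist(lapply(sets, `[[`, "labels"))
  trial_set(dat, labs, ref$fs, ref$channel_names, ref$n_classes,
            subject_id, ref$session_tag)
}

# rbind for 3-d arrays along the first dimension
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  n <- sum(vapply(parts, function(p) dim(p)[1L], integer(1)))
  out <- array(0, c(n, d[2L], d[3L]))
  at <- 0L
  for (p in parts) {
    np <- dim(p)[1L]
    if (np > 0L) out[at + seq_len(np), , ] <- p
    at <- at + np
  }
  out
}

CTNET_CONTAINER_FORMAT <- "ctnet-trialset"
CTNET_CONTAINER_VERSION <- 1L

#' Save a trial_set to a single-file container
#'
#' The container is a serialized archive with a versioned header
#' (`format = "ctnet-trialset"`, `version = 1`) holding the trial tensor,
#' labels, sampling rate, channel names and metadata. Round-trips are
#' bit-identical.
#'
#' @param ts a valid `trial_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_trialset <- function(ts, path) {
  validate_trial_set(ts)
  obj <- list(format = CTNET_CONTAINER_FORMAT,
              version = CTNET_CONTAINER_VERSION,
              data = ts$data, labels = ts$labels, fs = ts$fs,
              channel_names = ts$channel_names, n_classes = ts$n_classes,
              subject_id = ts$subject_id, session_tag = ts$session_tag,
              prediction_only = ts$prediction_only)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a trial_set container
#'
#' @param path path to a file written by [save_trialset()].
#' @return the stored `trial_set`.
#' @export
load_trialset <- function(path) {
  if (!file.exists(path)) stop("cannot read trial-set container: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt trial-set container `", path,
                                           "`: ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, CTNET_CONTAINER_FORMAT)) {
    stop("corrupt trial-set container: field `format` missing or wrong")
  }
  if (!identical(obj$version, CTNET_CONTAINER_VERSION)) {
    stop("corrupt trial-set container: field `version` is ",
         deparse(obj$version), ", expected ", CTNET_CONTAINER_VERSION)
  }
  for (f in c("data", "labels", "fs", "channel_names", "n_classes",
              "subject_id", "session_tag")) {
    if (is.null(obj[[f]])) stop("corrupt trial-set container: field `", f, "` missing")
  }
  trial_set(obj$data, obj$labels, obj$fs, obj$channel_names, obj$n_classes,
            obj$subject_id, obj$session_tag,
            prediction_only = isTRUE(obj$prediction_only))
}
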