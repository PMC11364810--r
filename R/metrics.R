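# Evaluation metrics and statistics: confusion matrices, accuracy, Cohen's
# kappa, cross-subject aggregation, Hedges' g, and the exact paired Wilcoxon
# signed-rank test.

#' Confusion matrix from label vectors
#'
#' @param true,pred integer vectors of 0-based class labels, equal length.
#' @param n_classes number of classes `N`.
#' @return `N x N` integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(true, pred, n_classes) {
  stopifnot(length(true) == length(pred))
  lv <- 0:(n_classes - 1L)
  cm <- table(factor(true, levels = lv), factor(pred, levels = lv))
  m <- matrix(as.integer(cm), n_classes, n_classes,
              dimnames = list(true = lv, pred = lv))
  m
}

#' Classification accuracy of a confusion matrix
#'
#' Fraction of correctly predicted trials: the trace over the total count
#' (equivalently (TP + TN) / (TP + TN + FP + FN) in the binary case).
#'
#' @param cm confusion matrix (rows = true, columns = predicted).
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("accuracy: empty confusion matrix")
  sum(diag(cm)) / tot
}

#' Cohen's kappa from an observed accuracy
#'
#' `kappa = (P_o - P_e) / (1 - P_e)`. By default the chance level `P_e` is
#' the balanced-class convention `1/N` — appropriate for the class-balanced
#' benchmark sessions and the convention used to report mean kappas alongside
#' mean accuracies (e.g. a 4-class mean accuracy of 82.52% maps to
#' kappa 0.7670).
#'
#' @param p_o observed accuracy in `[0, 1]`.
#' @param n_classes number of classes (`>= 2`).
#' @return kappa value (`<= 1`).
#' @export
kappa <- function(p_o, n_classes) {
  if (n_classes < 2L) stop("kappa: need at least 2 classes")
  if (any(p_o < 0 | p_o > 1)) stop("kappa: p_o must lie in [0, 1]")
  p_e <- 1 / n_classes
  (p_o - p_e) / (1 - p_e)
}

#' Cohen's kappa from a confusion matrix
#'
#' `pe_method = "balanced"` uses `P_e = 1/N`; `"marginal"` uses the
#' marginal-product chance agreement of the classical definition.
#'
#' @param cm confusion matrix.
#' @param pe_method chance-level convention.
#' @return kappa value.
#' @export
kappa_from_cm <- function(cm, pe_method = c("balanced", "marginal")) {
  pe_method <- match.arg(pe_method)
  tot <- sum(cm)
  if (tot == 0) stop("kappa_from_cm: empty confusion matrix")
  p_o <- sum(diag(cm)) / tot
  p_e <- if (pe_method == "balanced") 1 / nrow(cm)
         else sum(rowSums(cm) * colSums(cm)) / tot^2
  (p_o - p_e) / (1 - p_e)
}

#' Per-subject evaluation result
#'
#' @param subject_id subject label.
#' @param confusion confusion matrix of the subject's test set.
#' @param pe_method kappa chance convention (see [kappa_from_cm()]).
#' @return an object of class `subject_result` with fields `subject_id`,
#'   `confusion`, `accuracy`, `kappa`.
#' @export
subject_result <- function(subject_id, confusion, pe_method = "balanced") {
  structure(list(subject_id = subject_id, confusion = confusion,
                 accuracy = accuracy(confusion),
                 kappa = kappa_from_cm(confusion, pe_method)),
            class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> %s: accuracy %.2f%%, kappa %.4f (n = %d)\n",
              x$subject_id, 100 * x$accuracy, x$kappa, sum(x$confusion)))
  invisible(x)
}

#' Aggregate per-subject results
#'
#' Cross-subject summary in the reporting convention of the benchmark tables:
#' mean and sample standard deviation (n-1 denominator) of the per-subject
#' accuracy percentages, and the mean kappa. Values are stored at full
#' precision; the print method rounds to 2 decimals (accuracy) and 4
#' (kappa).
#'
#' @param results list of `subject_result`s (>= 2), or a numeric vector of
#'   accuracy percentages.
#' @param kappas optional numeric vector of per-subject kappas when
#'   `results` is a bare accuracy vector.
#' @return an object of class `aggregate_result` with fields
#'   `accuracies` (%), `mean_accuracy`, `sd_accuracy`, `mean_kappa`,
#'   `subject_ids`.
#' @export
aggregate_results <- function(results, kappas = NULL) {
  if (is.numeric(results)) {
    acc <- results
    ids <- names(results) %||% paste0("S", seq_along(results))
    if (is.null(kappas)) kappas <- rep(NA_real_, length(acc))
  } else {
    acc <- vapply(results, function(r) 100 * r$accuracy, numeric(1))
    kappas <- vapply(results, `[[`, numeric(1), "kappa")
    ids <- vapply(results, function(r) as.character(r$subject_id), character(1))
  }
  if (length(acc) < 2L) stop("aggregate_results: need >= 2 subjects for a std")
  structure(list(accuracies = acc, subject_ids = ids,
                 mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                 mean_kappa = mean(kappas)),
            class = "aggregate_result")
}

#' @export
print.aggregate_result <- function(x, ...) {
  cat(sprintf("<aggregate_result> %d subjects: %.2f +- %.2f %%",
              length(x$accuracies), x$mean_accuracy, x$sd_accuracy))
  if (!is.na(x$mean_kappa)) cat(sprintf(", mean kappa %.4f", x$mean_kappa))
  cat("\n")
  invisible(x)
}

#' Hedges' g effect size
#'
#' Cohen's d with the pooled standard deviation (n1 + n2 - 2 denominator),
#' corrected for small samples: `g = d * (1 - 3 / (4(n1 + n2) - 9))`. The
#' sign follows `x` minus `y`.
#'
#' @param x,y numeric vectors (each of length >= 2), e.g. per-subject
#'   accuracies of two model variants.
#' @return an object of class `effect_size_result` with `g`, `d`, the group
#'   means, standard deviations and sizes.
#' @export
hedges_g <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("hedges_g: both groups need >= 2 values")
  s1 <- stats::sd(x); s2 <- stats::sd(y)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("hedges_g: zero pooled variance")
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  g <- d * (1 - 3 / (4 * (n1 + n2) - 9))
  structure(list(g = g, d = d, mean1 = mean(x), mean2 = mean(y),
                 sd1 = s1, sd2 = s2, n1 = n1, n2 = n2),
            class = "effect_size_result")
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf("<effect_size> g = %.3f (d = %.3f; %.2f vs %.2f; n = %d, %d)\n",
              x$g, x$d, x$mean1, x$mean2, x$n1, x$n2))
  invisible(x)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Tests paired differences `x - y`. Zero differences are dropped; absolute
#' differences are ranked with midranks for ties; the p-value comes from the
#' exact null distribution of the signed-rank sum over all `2^n` equally
#' likely sign assignments — computed via its generating function, with no
#' normal approximation. `alternative = "greater"` tests for `x` tending to
#' exceed `y`; `"two_sided"` doubles the smaller tail (capped at 1).
#'
#' @param x,y paired numeric vectors of equal length (`n <= 25` after
#'   dropping zeros).
#' @param alternative `"greater"`, `"less"` or `"two_sided"`.
#' @return exact p-value.
#' @export
wilcoxon_exact_p <- function(x, y,
                             alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("wilcoxon_exact_p: all differences are zero; test undefined")
  if (n > 25L) stop("wilcoxon_exact_p: exact enumeration supported for n <= 25")
  r2 <- as.integer(round(2 * rank(abs(d))))   # doubled midranks are integers
  w_plus2 <- sum(r2[d > 0])
  # exact distribution of the doubled positive-rank sum: product of
  # (1 + z^r2_i) / 2 over observations, i.e. 2^n sign assignments
  tot <- sum(r2)
  pmf <- c(1, rep(0, tot))
  for (r in r2) {
    shifted <- c(rep(0, r), pmf[seq_len(tot + 1 - r)])
    pmf <- (pmf + shifted) / 2
  }
  p_ge <- sum(pmf[(w_plus2 + 1L):(tot + 1L)])
  p_le <- sum(pmf[seq_len(w_plus2 + 1L)])
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}
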