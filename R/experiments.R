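# Experiment orchestration: the augmentation x Transformer ablation grid and
# one-axis hyperparameter sweeps. Both run the subject-specific protocol per
# condition on caller-supplied per-subject train/test sets.

#' Ablation grid: augmentation x Transformer
#'
#' Runs the four conditions {WA, NA} x {WT, NT} — with/without S&R
#' augmentation crossed with with/without the Transformer encoder (NT builds
#' the model with `L = 0`, so the classifier receives the conv features
#' alone) — and computes Hedges' g for the five standard comparisons:
#' WA+WT vs WA+NT, NA+WT vs NA+NT, WT+WA vs WT+NA, NT+WA vs NT+NA, and
#' WA+WT vs NA+NT.
#'
#' @param train_sets,test_sets per-subject `trial_set` lists (matching order).
#' @param model_cfg a [model_config()] for the full (WT) model.
#' @param train_cfg a [train_config()]; its `augment` settings define the WA
#'   conditions, NA sets `multiplier = 0`.
#' @return an object of class `ablation_result`: `conditions` (named list of
#'   per-condition `subject_result` lists), `accuracy` (subjects x condition
#'   matrix, %), and `effect_sizes` (named list of `effect_size_result`).
#' @export
run_ablation <- function(train_sets, test_sets, model_cfg,
                         train_cfg = train_config("subject_specific")) {
  validate_model_config(model_cfg)
  no_tr <- model_cfg
  no_tr$L <- 0L
  no_aug <- train_cfg
  no_aug$augment$multiplier <- 0L
  grid <- list(
    WA_WT = list(m = model_cfg, t = train_cfg),
    WA_NT = list(m = no_tr,     t = train_cfg),
    NA_WT = list(m = model_cfg, t = no_aug),
    NA_NT = list(m = no_tr,     t = no_aug))
  conditions <- lapply(grid, function(g) {
    run_subject_specific(train_sets, test_sets, g$m, g$t)
  })
  acc <- vapply(conditions,
                function(rs) vapply(rs, function(r) 100 * r$accuracy, numeric(1)),
                numeric(length(train_sets)))
  acc <- matrix(acc, ncol = length(conditions),
                dimnames = list(vapply(test_sets, `[[`, "", "subject_id"),
                                names(conditions)))
  pairs <- list(
    "WA+WT vs WA+NT" = c("WA_WT", "WA_NT"),
    "NA+WT vs NA+NT" = c("NA_WT", "NA_NT"),
    "WT+WA vs WT+NA" = c("WA_WT", "NA_WT"),
    "NT+WA vs NT+NA" = c("WA_NT", "NA_NT"),
    "WA+WT vs NA+NT" = c("WA_WT", "NA_NT"))
  effects <- lapply(pairs, function(p) {
    tryCatch(hedges_g(acc[, p[1L]], acc[, p[2L]]),
             error = function(e) structure(
               list(g = 0, d = 0, note = conditionMessage(e)),
               class = "effect_size_result"))
  })
  structure(list(conditions = conditions, accuracy = acc,
                 effect_sizes = effects),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result> mean accuracy (%):\n")
  print(round(colMeans(x$accuracy), 2))
  cat("effect sizes (Hedges' g):\n")
  for (nm in names(x$effect_sizes)) {
    cat(sprintf("  %-16s g = %.3f\n", nm, x$effect_sizes[[nm]]$g))
  }
  invisible(x)
}

#' One-axis hyperparameter sweep
#'
#' Re-trains and evaluates the subject-specific protocol for each value of a
#' single architecture axis, everything else fixed: `"P2"` (second pooling
#' length; the implied token size is reported), `"heads"` (attention heads
#' `h`) or `"depth"` (encoder depth `L`).
#'
#' @param train_sets,test_sets per-subject `trial_set` lists.
#' @param model_cfg baseline [model_config()].
#' @param axis `"P2"`, `"heads"` or `"depth"`.
#' @param values vector of axis values; each must yield a valid
#'   configuration (e.g. at least one token, `d` divisible by `h`).
#' @param train_cfg a [train_config()].
#' @return data frame per value: `value`, `token_size`, `mean_accuracy`,
#'   `sd_accuracy`, `mean_kappa`.
#' @export
run_sweep <- function(train_sets, test_sets, model_cfg,
                      axis = c("P2", "heads", "depth"), values,
                      train_cfg = train_config("subject_specific")) {
  axis <- match.arg(axis)
  validate_model_config(model_cfg)
  if (length(values) == 0L) stop("run_sweep: no values supplied")
  cfgs <- lapply(values, function(v) {
    cfg <- model_cfg
    if (axis == "P2") cfg$P2 <- as.integer(v)
    if (axis == "heads") { cfg$h <- as.integer(v); cfg$d_k <- cfg$d %/% cfg$h }
    if (axis == "depth") cfg$L <- as.integer(v)
    validate_model_config(cfg)   # config error before any training starts
    cfg
  })
  rows <- lapply(seq_along(values), function(i) {
    cfg <- cfgs[[i]]
    res <- run_subject_specific(train_sets, test_sets, cfg, train_cfg)
    agg <- aggregate_results(res)
    data.frame(value = values[i],
               token_size = token_length(cfg$T_samples, cfg$P1, cfg$P2),
               mean_accuracy = agg$mean_accuracy,
               sd_accuracy = agg$sd_accuracy,
               mean_kappa = agg$mean_kappa)
  })
  out <- do.call(rbind, rows)
  attr(out, "axis") <- axis
  out
}

#' Reproducibility manifest for an experiment
#'
#' Captures the resolved model/training configuration, the seeds, and the
#' package version — enough to re-execute a run bit-for-bit.
#'
#' @param model_cfg a [model_config()]. @param train_cfg a [train_config()].
#' @param extra named list of additional fields (dataset source, protocol...).
#' @return a list with class `run_manifest`.
#' @export
run_manifest <- function(model_cfg, train_cfg, extra = list()) {
  structure(c(list(package_version =
                     as.character(utils::packageVersion("ctnet")),
                   model_config = unclass(model_cfg),
                   train_config = unclass(train_cfg)),
              extra),
            class = "run_manifest")
}
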