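test_that("stratified split reserves the validation fraction per class", {
  ts <- generate_mi_trials(synth_config(n_per_class = 25L, C = 2L,
                                        T_samples = 64L, n_classes = 4L,
                                        class_channel_map = list(1L, 2L, 1L, 2L),
                                        band = c(20, 60), seed = 3L))
  sp <- split_train_val(ts, 0.30, seed = 1)
  expect_identical(n_trials(sp$train), 70L)
  expect_identical(n_trials(sp$val), 30L)
  for (cls in 0:3) {
    nv <- sum(sp$val$labels == cls)
    expect_true(nv >= 7L && nv <= 8L)   # within 1 trial of 0.30 * 25
  }
  # disjoint and exhaustive
  fp_tr <- trial_fingerprints(sp$train)
  fp_va <- trial_fingerprints(sp$val)
  expect_length(intersect(fp_tr, fp_va), 0L)
  expect_setequal(c(fp_tr, fp_va), trial_fingerprints(ts))
  # determinism
  sp2 <- split_train_val(ts, 0.30, seed = 1)
  expect_identical(sp$val$data, sp2$val$data)
  sp3 <- split_train_val(ts, 0.30, seed = 2)
  expect_false(identical(sort(fp_va), sort(trial_fingerprints(sp3$val))))
  # error cases
  expect_error(split_train_val(ts, 0), "between 0 and 1")
  one_per_class <- subset_trials(ts, 1:4, prediction_only = FALSE)
  expect_error(split_train_val(one_per_class, 0.3), "at least 2")
})

test_that("cross-entropy matches its closed forms", {
  perfect <- diag(4)[c(1, 3), ]
  expect_equal(cross_entropy(perfect, c(0L, 2L)), 0, tolerance = 1e-9)
  expect_equal(cross_entropy(matrix(0.25, 3, 4), c(0L, 1L, 3L)), log(4),
               tolerance = 1e-12)
  yhat <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  expect_equal(cross_entropy(yhat, c(0L, 1L)), -(log(0.8) + log(0.6)) / 2,
               tolerance = 1e-12)
  expect_equal(cross_entropy(yhat, rbind(c(1, 0), c(0, 1))),
               0.3669845, tolerance = 1e-6)
  # zero probability at the true label is clamped, not infinite
  expect_true(is.finite(cross_entropy(rbind(c(0, 1)), 0L)))
})

test_that("fit keeps the bookkeeping contract and the best-validation snapshot", {
  ts <- zscore_trialset(tiny_trialset(n_per_class = 10L, effect = 2, seed = 8L))
  sp <- split_train_val(ts, 0.3, seed = 1)
  m <- build_model(tiny_model_config(), seed = 2)
  tc <- train_config(epochs = 4L, batch_size = 6L, seed = 5L,
                     augment = augment_config(multiplier = 0L))
  out <- fit(m, sp$train, sp$val, tc)
  expect_identical(nrow(out$history), 4L)
  expect_true(all(is.finite(out$history$val_loss)))
  # selected epoch minimizes the recorded validation loss
  expect_identical(out$selected_epoch, which.min(out$history$val_loss))
  # the returned snapshot reproduces that epoch's validation loss
  pv <- model_forward(out$model, sp$val)$probs
  expect_equal(cross_entropy(pv, sp$val$labels),
               min(out$history$val_loss), tolerance = 1e-9)
  # reproducibility: same seeds, same everything
  out2 <- fit(build_model(tiny_model_config(), seed = 2), sp$train, sp$val, tc)
  expect_identical(out2$history, out$history)
  expect_identical(ctnet:::flatten_params(out2$model$params),
                   ctnet:::flatten_params(out$model$params))
  expect_error(fit(m, subset_trials(sp$train, integer(0)), sp$val, tc), "empty")
})

test_that("subject-specific protocol scores each subject independently", {
  train_sets <- generate_mi_subjects(
    synth_config(n_per_class = 6L, C = 2L, T_samples = 64L,
                 band = c(20, 60), effect = 2), seeds = c(11L, 12L))
  test_sets <- generate_mi_subjects(
    synth_config(n_per_class = 4L, C = 2L, T_samples = 64L,
                 band = c(20, 60), effect = 2), seeds = c(21L, 22L))
  for (i in 1:2) test_sets[[i]]$session_tag <- "test"
  tc <- train_config(epochs = 2L, batch_size = 8L, seed = 3L,
                     augment = augment_config(K = 4L, multiplier = 1L, seed = 3L))
  res <- run_subject_specific(train_sets, test_sets, tiny_model_config(), tc)
  expect_length(res, 2L)
  for (i in 1:2) {
    expect_identical(sum(res[[i]]$confusion), n_trials(test_sets[[i]]))
    expect_identical(res[[i]]$subject_id, test_sets[[i]]$subject_id)
    # leakage audit: no test trial influenced training or model selection
    test_fp <- trial_fingerprints(zscore_trialset(test_sets[[i]]))
    expect_length(intersect(test_fp, res[[i]]$train_fingerprints), 0L)
  }
  # identical data with fixed seeds -> identical results
  res2 <- run_subject_specific(train_sets, test_sets, tiny_model_config(), tc)
  expect_identical(res2[[1]]$confusion, res[[1]]$confusion)
  # mismatched subject lists are refused
  expect_error(run_subject_specific(train_sets, rev(test_sets),
                                    tiny_model_config(), tc), "match")
  empty_test <- test_sets
  empty_test[[2]] <- subset_trials(test_sets[[2]], integer(0))
  expect_error(run_subject_specific(train_sets, empty_test,
                                    tiny_model_config(), tc), "empty")
})

test_that("LOSO never trains on the held-out subject", {
  sets <- generate_mi_subjects(
    synth_config(n_per_class = 5L, C = 2L, T_samples = 64L,
                 band = c(20, 60), effect = 2), seeds = c(1L, 2L, 3L))
  tc <- train_config("cross_subject", epochs = 2L, batch_size = 16L, seed = 7L,
                     augment = augment_config(K = 4L, multiplier = 0L))
  res <- run_loso(sets, tiny_model_config(dropout_profile = "cross_subject"), tc)
  expect_length(res, 3L)
  for (i in 1:3) {
    held_fp <- trial_fingerprints(zscore_trialset(sets[[i]]))
    expect_length(intersect(held_fp, res[[i]]$train_fingerprints), 0L)
    # and the training pool does come from the other subjects
    other_fp <- unlist(lapply(sets[-i], function(s)
      trial_fingerprints(zscore_trialset(s))))
    expect_true(all(res[[i]]$train_fingerprints %in% other_fp))
    expect_identical(sum(res[[i]]$confusion), n_trials(sets[[i]]))
  }
  expect_error(run_loso(sets[1L]), "at least 2")
  sets2 <- sets[1:2]
  sets2[[2]] <- subset_trials(sets2[[2]], integer(0))
  expect_error(run_loso(sets2,
                        tiny_model_config(dropout_profile = "cross_subject"),
                        tc), "empty")
})
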