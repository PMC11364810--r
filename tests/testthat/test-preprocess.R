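test_that("z-score standardization matches hand arithmetic and is idempotent", {
  trial <- matrix(c(1, 3, 5, 7), 2, 2, byrow = TRUE)  # [[1,3],[5,7]]
  z <- zscore_trial(trial)
  expect_equal(z, matrix(c(-3, -1, 1, 3) / sqrt(5), 2, 2, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-6)

  x <- matrix(rnorm(3 * 50, mean = 4, sd = 9), 3, 50)
  expect_equal(zscore_trial(zscore_trial(x)), zscore_trial(x), tolerance = 1e-9)
  expect_error(zscore_trial(matrix(5, 4, 10)), "degenerate")
})

test_that("S&R degenerate cases reproduce originals exactly", {
  ts <- tiny_trialset(n_per_class = 4L, seed = 3L)
  # K = 1: every artificial trial is bit-identical to some same-class original
  art <- segment_recombine(ts, augment_config(K = 1L, multiplier = 1L, seed = 5L))
  expect_identical(n_trials(art), n_trials(ts))
  orig_fp <- split(trial_fingerprints(ts), ts$labels)
  art_fp <- trial_fingerprints(art)
  for (j in seq_len(n_trials(art))) {
    expect_true(art_fp[j] %in% orig_fp[[as.character(art$labels[j])]])
  }
  # single trial per class: recombination is forced to reproduce it
  one <- subset_trials(ts, c(1L, 2L), prediction_only = FALSE)
  art1 <- segment_recombine(one, augment_config(K = 8L, multiplier = 2L, seed = 1L))
  for (j in seq_len(n_trials(art1))) {
    src <- which(one$labels == art1$labels[j])
    expect_identical(art1$data[j, , ], one$data[src, , ])
  }
})

test_that("every S&R segment traces back to a same-class original block", {
  ts <- generate_mi_trials(synth_config(n_per_class = 10L, C = 2L,
                                        T_samples = 1000L, seed = 9L))
  K <- 8L
  art <- segment_recombine(ts, augment_config(K = K, multiplier = 1L, seed = 2L))
  expect_identical(n_trials(art), n_trials(ts))
  seg_len <- 1000L %/% K
  for (j in seq_len(n_trials(art))) {
    for (k in seq_len(K)) {
      span <- ((k - 1L) * seg_len + 1L):(k * seg_len)
      block <- art$data[j, , span]
      # brute-force provenance search over *all* originals
      hits <- vapply(seq_len(n_trials(ts)), function(i) {
        identical(ts$data[i, , span], block)
      }, logical(1))
      expect_true(any(hits))
      # continuous-valued segments are unique, so provenance reveals the
      # class: it must never be a different one
      expect_true(all(ts$labels[hits] == art$labels[j]))
    }
  }
})

test_that("S&R respects label proportions, determinism and its error cases", {
  ts <- generate_mi_trials(synth_config(n_per_class = 4L, C = 2L,
                                        T_samples = 64L, n_classes = 2L,
                                        band = c(20, 60), seed = 13L))
  unbalanced <- subset_trials(ts, c(1:6, 8L), prediction_only = FALSE)
  art <- segment_recombine(unbalanced, augment_config(K = 4L, multiplier = 3L, seed = 1L))
  expect_identical(as.integer(table(art$labels)),
                   3L * as.integer(table(unbalanced$labels)))
  again <- segment_recombine(unbalanced, augment_config(K = 4L, multiplier = 3L, seed = 1L))
  expect_identical(art$data, again$data)

  expect_error(segment_recombine(ts, augment_config(K = 7L)), "divisible")
  only0 <- subset_trials(ts, which(ts$labels == 0L), prediction_only = TRUE)
  expect_error(segment_recombine(only0, augment_config(K = 4L)), "no trials")
  expect_error(augment_config(K = 0L), "K")
  expect_error(augment_config(multiplier = -1L), "multiplier")
})

test_that("augment_training_set appends multiplier x originals (0 = no-op)", {
  ts <- tiny_trialset(n_per_class = 3L, seed = 2L)
  expect_identical(augment_training_set(ts, augment_config(multiplier = 0L)), ts)
  aug <- augment_training_set(ts, augment_config(K = 8L, multiplier = 2L, seed = 3L))
  expect_identical(n_trials(aug), 3L * n_trials(ts))
  expect_identical(aug$data[seq_len(n_trials(ts)), , ], ts$data)
})
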