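test_that("token_length reproduces the pooling arithmetic", {
  expect_identical(token_length(1000, 8, 8), 15L)
  expect_identical(token_length(1000, 8, 6), 20L)
  expect_identical(token_length(1000, 8, 1), 125L)
  expect_identical(token_length(1000, 8, 10), 12L)
  expect_error(token_length(0, 8, 8), "positive")
  # matches the actual forward-pass token count across a sweep
  for (P2 in c(1L, 2L, 3L, 5L)) {
    cfg <- model_config(C = 2, T_samples = 60, N = 2, F1 = 2, Kc1 = 8, D = 2,
                        Kc2 = 4, P1 = 4, P2 = P2, h = 2, L = 0)
    m <- build_model(cfg)
    S <- conv_forward(m, matrix(rnorm(120), 2, 60))
    expect_identical(nrow(S), token_length(60, 4, P2))
    expect_identical(ncol(S), cfg$d)
  }
})

test_that("build_model honours shape contracts and rejects bad configs", {
  m2a <- build_model(model_config(22, 1000, 4))
  fw <- model_forward(m2a, array(rnorm(5 * 22 * 1000), c(5, 22, 1000)))
  expect_identical(dim(fw$logits), c(5L, 4L))
  expect_equal(rowSums(fw$probs), rep(1, 5), tolerance = 1e-9)

  m2b <- build_model(model_config(3, 1000, 2))
  fw2 <- model_forward(m2b, array(rnorm(2 * 3 * 1000), c(2, 3, 1000)))
  expect_identical(dim(fw2$logits), c(2L, 2L))

  expect_error(model_config(3, 1000, 2, F1 = 8, D = 2, h = 3), "divisible")
  expect_error(model_config(3, 30, 2, P1 = 8, P2 = 8), "P1 \\* P2|tokens")
  expect_error(model_forward(m2b, matrix(0, 4, 1000)), "shape")
})

test_that("conv module matches the printed feature geometry and stays finite", {
  m <- build_model(model_config(22, 1000, 4))
  S <- conv_forward(m, matrix(rnorm(22 * 1000), 22, 1000))
  expect_identical(dim(S), c(15L, 16L))
  mP6 <- build_model(model_config(22, 1000, 4, P2 = 6))
  expect_identical(dim(conv_forward(mP6, matrix(rnorm(22000), 22, 1000))),
                   c(20L, 16L))
  # zero input: inference-mode batch norm uses stored statistics
  expect_true(all(is.finite(conv_forward(m, matrix(0, 22, 1000)))))
})

test_that("attention weights are row-stochastic; identical tokens attend uniformly", {
  m <- build_model(model_config(3, 1000, 2), seed = 5)
  S <- conv_forward(m, matrix(rnorm(3000), 3, 1000))
  out <- encoder_forward(m, S, return_attention = TRUE)
  for (A in out$attention) {           # Tc x Tc x h x 1 per layer
    expect_true(all(A >= 0))
    expect_equal(apply(A, c(1, 3, 4), sum),
                 array(1, dim(A)[c(1, 3, 4)]), tolerance = 1e-6)
  }
  Tc <- nrow(S)
  S_same <- matrix(rep(S[1, ], each = Tc), Tc, ncol(S))
  A1 <- encoder_forward(m, S_same, return_attention = TRUE)$attention[[1]]
  expect_equal(A1[, , 1, 1], matrix(1 / Tc, Tc, Tc), tolerance = 1e-9)
  expect_true(all(is.finite(out$E)))
})

test_that("encoder agrees with a literal step-by-step transcription", {
  # tiny single-head single-layer config plus the full default, both checked
  cfg_small <- model_config(C = 2, T_samples = 24, N = 2, F1 = 1, Kc1 = 4,
                            D = 2, Kc2 = 3, P1 = 4, P2 = 2, h = 1, L = 1,
                            ffn_mult = 2)
  for (cfg in list(cfg_small, model_config(3, 1000, 2))) {
    m <- build_model(cfg, seed = 8)
    Tc <- token_length(cfg$T_samples, cfg$P1, cfg$P2)
    set.seed(42)
    S <- matrix(rnorm(Tc * cfg$d), Tc, cfg$d)
    expect_equal(encoder_forward(m, S), reference_encoder(m, S),
                 tolerance = 1e-6)
  }
})

test_that("gelu is the exact Gaussian-CDF form", {
  expect_identical(gelu(0), 0)
  expect_equal(gelu(10), 10, tolerance = 1e-6)
  expect_equal(gelu(1), stats::pnorm(1), tolerance = 1e-12)
  expect_equal(gelu(1), 0.841345, tolerance = 1e-6)
  x <- seq(-4, 4, by = 0.25)
  expect_equal(gelu(x), x * 0.5 * (1 + pracma::erf(x / sqrt(2))),
               tolerance = 1e-12)
})

test_that("classifier fuses S and E additively and normalizes", {
  m <- build_model(model_config(22, 1000, 4), seed = 2)
  S <- conv_forward(m, matrix(rnorm(22000), 22, 1000))
  E <- encoder_forward(m, S)
  lg <- classify(m, S, E)
  expect_length(lg, 4L)
  expect_identical(length(m$params$clf$W), 240L * 4L)  # flattened 240 -> 4
  # E = 0 is the conv-features-only ablation path
  lg0 <- classify(m, S, 0)
  expect_equal(lg0, classify(m, S, matrix(0, nrow(S), ncol(S))))
  p <- exp(lg - max(lg)) / sum(exp(lg - max(lg)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("parameter counts match the closed-form accounting", {
  expect_identical(count_parameters(build_model(model_config(22, 1000, 4))), 25684L)
  expect_identical(count_parameters(build_model(model_config(3, 1000, 2))), 24898L)
  # conv + classifier only (encoder ablated)
  expect_identical(count_parameters(build_model(model_config(22, 1000, 4, L = 0))),
                   5040L + 964L)
  # randomized configuration sweep against the closed form
  set.seed(31)
  for (i in 1:12) {
    F1 <- sample(c(2L, 4L, 8L), 1)
    D <- sample(1:2, 1)
    d <- F1 * D
    hs <- Filter(function(h) d %% h == 0L, 1:4)
    cfg <- model_config(C = sample(2:23, 1), T_samples = 250L,
                        N = sample(2:4, 1), F1 = F1, D = D,
                        Kc1 = sample(c(8L, 16L, 33L), 1),
                        Kc2 = sample(c(4L, 7L), 1), P1 = 5L,
                        P2 = sample(2:5, 1), h = sample(hs, 1),
                        L = sample(0:3, 1), ffn_mult = sample(2:4, 1))
    expect_identical(count_parameters(build_model(cfg)),
                     as.integer(param_count_formula(cfg)))
  }
  acc <- parameter_accounting(build_model(model_config(22, 1000, 4)))
  expect_identical(unname(acc["total"]), 25684L)
  expect_identical(unname(acc["conv_module"]), 5040L)
  expect_identical(unname(acc["encoder_layer_1"]), 3280L)
  expect_identical(unname(acc["classifier"]), 964L)
})

test_that("inference is deterministic and checkpoints round-trip", {
  m <- build_model(model_config(3, 1000, 2), seed = 4)
  X <- array(rnorm(3 * 3 * 1000), c(3, 3, 1000))
  f1 <- model_forward(m, X)
  f2 <- model_forward(m, X)
  expect_identical(f1$logits, f2$logits)   # dropout off in eval mode
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(model_forward(m2, X)$logits, f1$logits)
  saveRDS(list(bogus = 1), path)
  expect_error(load_checkpoint(path), "corrupt")
})
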