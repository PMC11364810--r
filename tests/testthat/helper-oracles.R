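# Independent reference implementations used as oracles. These deliberately
# avoid the package's computational paths: convolutions by triple loop,
# spectra via stats::spec.pgram, the encoder as a literal per-equation
# transcription, Wilcoxon by direct sign enumeration, parameter counts in
# closed form.

# small geometry that keeps training tests fast
tiny_model_config <- function(...) {
  model_config(C = 2, T_samples = 64, N = 2, F1 = 4, Kc1 = 16, D = 2,
               Kc2 = 8, P1 = 4, P2 = 4, h = 2, L = 2, ffn_mult = 2, ...)
}

tiny_trialset <- function(n_per_class = 6L, effect = 1, seed = 1L,
                          C = 2L, T_samples = 64L, n_classes = 2L) {
  generate_mi_trials(synth_config(
    n_per_class = n_per_class, C = C, T_samples = T_samples, fs = 250,
    n_classes = n_classes, band = c(20, 60), effect = effect, seed = seed))
}

# triple-loop 'same'-padded cross-correlation
naive_conv1d <- function(X, W) {
  dX <- dim(X); K <- dim(W)[1L]; Min <- dim(W)[2L]; Mout <- dim(W)[3L]
  pl <- (K - 1L) %/% 2L
  Xp <- array(0, c(dX[1L], dX[2L] + K - 1L, Min))
  Xp[, pl + seq_len(dX[2L]), ] <- X
  Y <- array(0, c(dX[1L], dX[2L], Mout))
  for (r in seq_len(dX[1L])) for (t in seq_len(dX[2L])) for (o in seq_len(Mout)) {
    s <- 0
    for (m in seq_len(Min)) for (k in seq_len(K)) {
      s <- s + Xp[r, t + k - 1L, m] * W[k, m, o]
    }
    Y[r, t, o] <- s
  }
  Y
}

# periodogram band power (mean spectral density inside the band), per trial
periodogram_band_power <- function(x, fs, band) {
  sp <- stats::spec.pgram(x, taper = 0, detrend = FALSE, plot = FALSE)
  f_hz <- sp$freq * fs
  keep <- f_hz >= band[1] & f_hz <= band[2]
  mean(sp$spec[keep])
}

class_band_power <- function(ts, channel, band) {
  p <- vapply(seq_len(n_trials(ts)),
              function(i) periodogram_band_power(ts$data[i, channel, ], ts$fs, band),
              numeric(1))
  split(p, ts$labels)
}

# literal transcription of the encoder equations: per-head projections,
# scaled dot-product attention, concatenation + output projection, post-norm
# residuals, position-wise feed forward with exact GELU
reference_encoder <- function(model, S) {
  cfg <- model$config
  eps <- 1e-5
  ln <- function(X, g, b) {
    t(apply(X, 1L, function(row) {
      (row - mean(row)) / sqrt(mean((row - mean(row))^2) + eps) * g + b
    }))
  }
  softmax <- function(v) { e <- exp(v - max(v)); e / sum(e) }
  X <- S
  for (p in model$params$enc) {
    heads <- lapply(seq_len(cfg$h), function(i) {
      cols <- (i - 1L) * cfg$d_k + seq_len(cfg$d_k)
      Qi <- X %*% p$WQ[, cols] + matrix(p$bQ[cols], nrow(X), cfg$d_k, byrow = TRUE)
      Ki <- X %*% p$WK[, cols] + matrix(p$bK[cols], nrow(X), cfg$d_k, byrow = TRUE)
      Vi <- X %*% p$WV[, cols] + matrix(p$bV[cols], nrow(X), cfg$d_k, byrow = TRUE)
      A <- t(apply(Qi %*% t(Ki) / sqrt(cfg$d_k), 1L, softmax))
      A %*% Vi
    })
    mha <- do.call(cbind, heads) %*% p$WO +
      matrix(p$bO, nrow(X), cfg$d, byrow = TRUE)
    O <- ln(mha + X, p$ln1_g, p$ln1_b)
    H <- O %*% p$W1 + matrix(p$b1, nrow(O), length(p$b1), byrow = TRUE)
    PF <- (H * stats::pnorm(H)) %*% p$W2 +
      matrix(p$b2, nrow(O), cfg$d, byrow = TRUE)
    X <- ln(PF + O, p$ln2_g, p$ln2_b)
  }
  X
}

# exact Wilcoxon by direct enumeration of all 2^n sign assignments
brute_wilcoxon <- function(x, y, alternative) {
  d <- (x - y)[x != y]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  switch(alternative,
         greater = p_ge, less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}

# closed-form parameter accounting: convolutions bias-free (each followed by
# batch norm with affine terms), attention/feed-forward linears with biases,
# two layer norms per encoder layer, single fully connected classifier
param_count_formula <- function(cfg) {
  conv <- cfg$F1 * cfg$Kc1 + 2 * cfg$F1 +
    cfg$C * cfg$F1 * cfg$D + 2 * cfg$F2 +
    cfg$Kc2 * cfg$F2 * cfg$F2 + 2 * cfg$F2
  ffn <- cfg$ffn_mult * cfg$d
  enc <- 3 * (cfg$d * cfg$d + cfg$d) + (cfg$d * cfg$d + cfg$d) +
    2 * cfg$d + (cfg$d * ffn + ffn) + (ffn * cfg$d + cfg$d) + 2 * cfg$d
  tc <- token_length(cfg$T_samples, cfg$P1, cfg$P2)
  clf <- tc * cfg$d * cfg$N + cfg$N
  conv + cfg$L * enc + clf
}
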