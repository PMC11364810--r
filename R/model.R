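# The CTNet architecture: an EEGNet-style convolutional feature extractor,
# a post-norm Transformer encoder, and a residual-fused linear classifier.

#' Token count after the two average-pooling stages
#'
#' The convolutional module pools the time axis twice (lengths `P1` then
#' `P2`), each stage discarding the remainder, so the Transformer sees
#' `floor(floor(T/P1)/P2)` tokens. For the benchmark geometry (`T = 1000`,
#' `P1 = 8`) this gives 15/20/125/12 tokens at `P2` = 8/6/1/10.
#'
#' @param T_samples trial length in samples.
#' @param P1,P2 pooling lengths.
#' @return integer token count.
#' @export
token_length <- function(T_samples, P1, P2) {
  if (T_samples < 1 || P1 < 1 || P2 < 1) {
    stop("token_length: all arguments must be positive")
  }
  (as.integer(T_samples) %/% as.integer(P1)) %/% as.integer(P2)
}

#' Architecture hyperparameters
#'
#' Collects every architecture setting: the defaults are the global
#' hyperparameters used for all subjects on the BCI IV benchmarks
#' (`F1 = 8, Kc1 = 64, D = 2, F2 = 16, Kc2 = 16, P1 = P2 = 8, h = 2, L = 6`).
#' The embedding size `d` equals `F2 = F1 * D` and each head gets
#' `d_k = d / h` dimensions. `dropout_profile = "cross_subject"` lowers the
#' convolutional dropout `p1` from 0.5 to 0.25 for the larger pooled training
#' sets.
#'
#' @param C input channels; `T_samples` input samples; `N` classes.
#' @param F1 temporal filters. @param Kc1 temporal kernel length (one-fourth
#'   of the sampling rate by default). @param D depth multiplier of the
#'   channel depth-wise convolution. @param Kc2 spatial-convolution kernel
#'   length. @param P1,P2 average-pooling lengths. @param h attention heads.
#' @param L encoder depth (number of identical layers; 0 removes the encoder).
#' @param ffn_mult feed-forward expansion factor (hidden width `ffn_mult * d`).
#' @param p1 convolutional-module dropout; defaults by `dropout_profile`.
#' @param p2 classifier dropout. @param p_ffn feed-forward dropout.
#' @param dropout_profile `"subject_specific"` (p1 = 0.5) or
#'   `"cross_subject"` (p1 = 0.25).
#' @param bn_momentum,bn_eps batch-norm running-statistics momentum and
#'   variance floor (framework defaults, recorded for reproducibility).
#' @return an object of class `model_config`.
#' @export
model_config <- function(C, T_samples, N, F1 = 8L, Kc1 = 64L, D = 2L,
                         Kc2 = 16L, P1 = 8L, P2 = 8L, h = 2L, L = 6L,
                         ffn_mult = 4L, p1 = NULL, p2 = 0.5, p_ffn = 0.5,
                         dropout_profile = c("subject_specific", "cross_subject"),
                         bn_momentum = 0.1, bn_eps = 1e-5) {
  dropout_profile <- match.arg(dropout_profile)
  if (is.null(p1)) p1 <- if (dropout_profile == "subject_specific") 0.5 else 0.25
  F2 <- F1 * D
  cfg <- structure(
    list(C = as.integer(C), T_samples = as.integer(T_samples), N = as.integer(N),
         F1 = as.integer(F1), Kc1 = as.integer(Kc1), D = as.integer(D),
         F2 = as.integer(F2), Kc2 = as.integer(Kc2), P1 = as.integer(P1),
         P2 = as.integer(P2), h = as.integer(h), L = as.integer(L),
         d = as.integer(F2), d_k = as.integer(F2) %/% as.integer(h),
         ffn_mult = as.integer(ffn_mult), p1 = p1, p2 = p2, p_ffn = p_ffn,
         dropout_profile = dropout_profile,
         bn_momentum = bn_momentum, bn_eps = bn_eps),
    class = "model_config")
  validate_model_config(cfg)
  cfg
}

validate_model_config <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  if (cfg$d != cfg$F1 * cfg$D) stop("model_config: d must equal F1 * D")
  if (cfg$d %% cfg$h != 0L) {
    stop("model_config: embedding size ", cfg$d, " not divisible by h = ", cfg$h)
  }
  if (cfg$T_samples < cfg$P1 * cfg$P2) {
    stop("model_config: T must be at least P1 * P2")
  }
  if (token_length(cfg$T_samples, cfg$P1, cfg$P2) < 1L) {
    stop("model_config: zero tokens after pooling")
  }
  for (p in c(cfg$p1, cfg$p2, cfg$p_ffn)) {
    if (p < 0 || p >= 1) stop("model_config: dropout probabilities must lie in [0, 1)")
  }
  if (cfg$L < 0L) stop("model_config: L must be >= 0")
  invisible(cfg)
}

glorot <- function(dims, fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -a, a), dims)
}

#' Build a CTNet model
#'
#' Initializes all trainable parameters (Glorot-uniform weights, zero biases,
#' unit batch-norm/layer-norm gains) and the batch-norm running statistics.
#' Construction is deterministic given `seed`. Convolutions carry no bias
#' (each is followed by batch norm); attention and feed-forward linear layers
#' do carry biases. No positional encoding is added to the token sequence.
#'
#' @param cfg a [model_config()].
#' @param seed RNG seed for the weight initialization.
#' @return an object of class `ctnet_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  validate_model_config(cfg)
  d <- cfg$d
  with_local_seed(seed, {
    params <- list(
      conv = list(
        Wt = glorot(c(cfg$Kc1, 1L, cfg$F1), cfg$Kc1, cfg$F1),
        bn1_g = rep(1, cfg$F1), bn1_b = rep(0, cfg$F1),
        Wd = glorot(c(cfg$C, cfg$F1, cfg$D), cfg$C, cfg$D),
        bn2_g = rep(1, cfg$F2), bn2_b = rep(0, cfg$F2),
        Ws = glorot(c(cfg$Kc2, cfg$F2, cfg$F2),
                    cfg$Kc2 * cfg$F2, cfg$Kc2 * cfg$F2),
        bn3_g = rep(1, cfg$F2), bn3_b = rep(0, cfg$F2)),
      enc = lapply(seq_len(cfg$L), function(l) list(
        WQ = glorot(c(d, d), d, d), bQ = rep(0, d),
        WK = glorot(c(d, d), d, d), bK = rep(0, d),
        WV = glorot(c(d, d), d, d), bV = rep(0, d),
        WO = glorot(c(d, d), d, d), bO = rep(0, d),
        ln1_g = rep(1, d), ln1_b = rep(0, d),
        W1 = glorot(c(d, cfg$ffn_mult * d), d, cfg$ffn_mult * d),
        b1 = rep(0, cfg$ffn_mult * d),
        W2 = glorot(c(cfg$ffn_mult * d, d), cfg$ffn_mult * d, d),
        b2 = rep(0, d),
        ln2_g = rep(1, d), ln2_b = rep(0, d))),
      clf = list(
        W = glorot(c(token_length(cfg$T_samples, cfg$P1, cfg$P2) * d, cfg$N),
                   token_length(cfg$T_samples, cfg$P1, cfg$P2) * d, cfg$N),
        b = rep(0, cfg$N)))
    buffers <- list(
      bn1 = list(mean = rep(0, cfg$F1), var = rep(1, cfg$F1)),
      bn2 = list(mean = rep(0, cfg$F2), var = rep(1, cfg$F2)),
      bn3 = list(mean = rep(0, cfg$F2), var = rep(1, cfg$F2)))
    structure(list(config = cfg, params = params, buffers = buffers,
                   init_seed = as.integer(seed)),
              class = "ctnet_model")
  })
}

#' Alias for [build_model()]
#' @inheritParams build_model
#' @return an object of class `ctnet_model`.
#' @export
ctnet <- function(cfg, seed = 1L) build_model(cfg, seed)

#' @export
print.ctnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ctnet_model> C=%d T=%d N=%d | F1=%d D=%d F2=%d | h=%d L=%d | tokens=%d x d=%d\n",
              cfg$C, cfg$T_samples, cfg$N, cfg$F1, cfg$D, cfg$F2, cfg$h, cfg$L,
              token_length(cfg$T_samples, cfg$P1, cfg$P2), cfg$d))
  cat(sprintf("  trainable parameters: %d\n", count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars, including batch-norm and layer-norm
#' affine terms. The benchmark configurations give 25,684 (22 channels,
#' 4 classes) and 24,898 (3 channels, 2 classes), i.e. 25.7 k / 24.9 k.
#'
#' @param model a `ctnet_model`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "ctnet_model"))
  length(unlist(model$params, recursive = TRUE, use.names = FALSE))
}

#' Per-component parameter accounting
#'
#' Breaks [count_parameters()] down by module: convolutional front end, each
#' encoder layer, classifier head.
#'
#' @param model a `ctnet_model`.
#' @return named integer vector of per-component counts.
#' @export
parameter_accounting <- function(model) {
  stopifnot(inherits(model, "ctnet_model"))
  n_of <- function(x) sum(vapply(x, length, integer(1)))
  out <- c(conv_module = n_of(model$params$conv))
  for (l in seq_along(model$params$enc)) {
    out[paste0("encoder_layer_", l)] <- n_of(model$params$enc[[l]])
  }
  out["classifier"] <- n_of(model$params$clf)
  out["total"] <- sum(out)
  out
}

# coerce a single (C, T) trial or (B, C, T) batch to a batch array
as_batch <- function(x, cfg) {
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  d <- dim(x)
  if (length(d) != 3L || d[2L] != cfg$C || d[3L] != cfg$T_samples) {
    stop("input shape (", paste(d, collapse = ", "),
         ") does not match model (C = ", cfg$C, ", T = ", cfg$T_samples, ")")
  }
  x
}

# ---- convolutional module ---------------------------------------------------
# Returns tokens (B, Tc, d) plus caches for backward when training.

conv_module_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  B <- dim(X)[1L]
  cache <- list(B = B)
  Xmat <- matrix(X, B * cfg$C, cfg$T_samples)       # rows b + (c-1)*B
  c1 <- conv1d_same_forward(array(Xmat, c(B * cfg$C, cfg$T_samples, 1L)),
                            model$params$conv$Wt)
  bn1 <- batchnorm_forward(c1$out, model$params$conv$bn1_g,
                           model$params$conv$bn1_b, model$buffers$bn1,
                           training, cfg$bn_momentum, cfg$bn_eps)
  dw <- depthwise_forward(bn1$out, model$params$conv$Wd, B)
  bn2 <- batchnorm_forward(dw$out, model$params$conv$bn2_g,
                           model$params$conv$bn2_b, model$buffers$bn2,
                           training, cfg$bn_momentum, cfg$bn_eps)
  e1 <- elu_forward(bn2$out)
  p1 <- avgpool_forward(e1, cfg$P1)
  dr1 <- dropout_forward(p1$out, cfg$p1, training)
  c2 <- conv1d_same_forward(dr1$out, model$params$conv$Ws)
  bn3 <- batchnorm_forward(c2$out, model$params$conv$bn3_g,
                           model$params$conv$bn3_b, model$buffers$bn3,
                           training, cfg$bn_momentum, cfg$bn_eps)
  e2 <- elu_forward(bn3$out)
  p2 <- avgpool_forward(e2, cfg$P2)
  dr2 <- dropout_forward(p2$out, cfg$p1, training)
  cache <- c(cache, list(c1 = c1$cache, bn1 = bn1$cache, dw = dw$cache,
                         bn2 = bn2$cache, bn2_out = bn2$out, e1 = e1,
                         p1 = p1$cache, dr1 = dr1$cache, c2 = c2$cache,
                         bn3 = bn3$cache, bn3_out = bn3$out, e2 = e2,
                         p2 = p2$cache, dr2 = dr2$cache))
  buffers <- list(bn1 = bn1$running, bn2 = bn2$running, bn3 = bn3$running)
  list(out = dr2$out, cache = cache, buffers = buffers)
}

conv_module_backward <- function(model, dS, cache) {
  cfg <- model$config
  g <- list()
  d2 <- dropout_backward(dS, cache$dr2)
  d2 <- avgpool_backward(d2, cache$p2)
  d2 <- elu_backward(cache$bn3_out, cache$e2, d2)
  b3 <- batchnorm_backward(d2, cache$bn3)
  g$bn3_g <- b3$dgamma; g$bn3_b <- b3$dbeta
  cb2 <- conv1d_same_backward(b3$dX, cache$c2, need_dx = TRUE)
  g$Ws <- cb2$dW
  d1 <- dropout_backward(cb2$dX, cache$dr1)
  d1 <- avgpool_backward(d1, cache$p1)
  d1 <- elu_backward(cache$bn2_out, cache$e1, d1)
  b2 <- batchnorm_backward(d1, cache$bn2)
  g$bn2_g <- b2$dgamma; g$bn2_b <- b2$dbeta
  dwb <- depthwise_backward(b2$dX, cache$dw)
  g$Wd <- dwb$dW
  b1 <- batchnorm_backward(dwb$dX, cache$bn1)
  g$bn1_g <- b1$dgamma; g$bn1_b <- b1$dbeta
  cb1 <- conv1d_same_backward(b1$dX, cache$c1, need_dx = FALSE)
  g$Wt <- cb1$dW
  g
}

# ---- transformer encoder ----------------------------------------------------
# X: (B*Tc, d) token matrix. Post-norm layers: O = LN(MHA(x) + x),
# E = LN(FFN(O) + O); FFN = linear -> GELU -> dropout -> linear.

encoder_layer_forward <- function(p, X, cfg, B, Tc, training) {
  att <- attention_forward(X, p, B, Tc, cfg$h, cfg$d_k)
  r1 <- att$out + X
  ln1 <- layernorm_forward(r1, p$ln1_g, p$ln1_b)
  l1 <- linear_forward(ln1$out, p$W1, p$b1)
  ge <- gelu(l1$out)
  dr <- dropout_forward(ge, cfg$p_ffn, training)
  l2 <- linear_forward(dr$out, p$W2, p$b2)
  r2 <- l2$out + ln1$out
  ln2 <- layernorm_forward(r2, p$ln2_g, p$ln2_b)
  list(out = ln2$out, attn = att$attn,
       cache = list(att = att$cache, ln1 = ln1$cache, l1 = l1$cache,
                    h_pre = l1$out, dr = dr$cache, l2 = l2$cache,
                    ln2 = ln2$cache))
}

encoder_layer_backward <- function(dE, cache) {
  g <- list()
  b2 <- layernorm_backward(dE, cache$ln2)
  g$ln2_g <- b2$dgamma; g$ln2_b <- b2$dbeta
  lb2 <- linear_backward(b2$dX, cache$l2)
  g$W2 <- lb2$dW; g$b2 <- lb2$db
  dge <- dropout_backward(lb2$dX, cache$dr)
  dh <- gelu_backward(cache$h_pre, dge)
  lb1 <- linear_backward(dh, cache$l1)
  g$W1 <- lb1$dW; g$b1 <- lb1$db
  dO <- lb1$dX + b2$dX  # residual: E = LN(FFN(O) + O)
  b1 <- layernorm_backward(dO, cache$ln1)
  g$ln1_g <- b1$dgamma; g$ln1_b <- b1$dbeta
  ab <- attention_backward(b1$dX, cache$att)
  g$WQ <- ab$dWQ; g$bQ <- ab$dbQ; g$WK <- ab$dWK; g$bK <- ab$dbK
  g$WV <- ab$dWV; g$bV <- ab$dbV; g$WO <- ab$dWO; g$bO <- ab$dbO
  list(dX = ab$dX + b1$dX, grads = g)   # residual: O = LN(MHA(X) + X)
}

# ---- full model forward/backward --------------------------------------------

ctnet_full_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  X <- as_batch(X, cfg)
  B <- dim(X)[1L]
  Tc <- token_length(cfg$T_samples, cfg$P1, cfg$P2)
  conv <- conv_module_forward(model, X, training)
  Sm <- matrix(conv$out, B * Tc, cfg$d)   # rows b + (t-1)*B
  Xl <- Sm
  enc_caches <- vector("list", cfg$L)
  attn <- vector("list", cfg$L)
  for (l in seq_len(cfg$L)) {
    st <- encoder_layer_forward(model$params$enc[[l]], Xl, cfg, B, Tc, training)
    enc_caches[[l]] <- st$cache
    attn[[l]] <- st$attn
    Xl <- st$out
  }
  E <- if (cfg$L > 0L) Xl else matrix(0, nrow(Sm), ncol(Sm))
  Fm <- Sm + E
  Fl <- matrix(array(Fm, c(B, Tc, cfg$d)), B, Tc * cfg$d)
  drc <- dropout_forward(Fl, cfg$p2, training)
  logit <- linear_forward(drc$out, model$params$clf$W, model$params$clf$b)
  list(logits = logit$out, S = Sm, E = E, attn = attn, buffers = conv$buffers,
       cache = list(conv = conv$cache, enc = enc_caches, drc = drc$cache,
                    logit = logit$cache, B = B, Tc = Tc))
}

ctnet_full_backward <- function(model, dlogits, cache) {
  cfg <- model$config
  B <- cache$B; Tc <- cache$Tc
  lb <- linear_backward(dlogits, cache$logit)
  grads <- list(clf = list(W = lb$dW, b = lb$db))
  dFl <- dropout_backward(lb$dX, cache$drc)
  dFm <- matrix(array(dFl, c(B, Tc, cfg$d)), B * Tc, cfg$d)
  dSm <- dFm                       # direct residual path S + E
  dE <- dFm
  grads$enc <- vector("list", cfg$L)
  if (cfg$L > 0L) {
    dX <- dE
    for (l in rev(seq_len(cfg$L))) {
      bl <- encoder_layer_backward(dX, cache$enc[[l]])
      grads$enc[[l]] <- bl$grads
      dX <- bl$dX
    }
    dSm <- dSm + dX                # encoder input is S as well
  }
  dS <- array(dSm, c(B, Tc, cfg$d))
  grads$conv <- conv_module_backward(model, dS, cache$conv)
  grads
}

#' Convolutional-module features of a trial
#'
#' Runs only the convolutional front end and returns the token sequence `S`
#' (`Tc x d` for a single trial, `B x Tc x d` for a batch). Inference mode:
#' batch norm uses the stored running statistics and dropout is off, so the
#' output is deterministic.
#'
#' @param model a `ctnet_model`.
#' @param trial a `C x T` matrix or a `B x C x T` array.
#' @return feature matrix `Tc x d` (or array `B x Tc x d`).
#' @export
conv_forward <- function(model, trial) {
  cfg <- model$config
  single <- is.matrix(trial)
  X <- as_batch(trial, cfg)
  out <- conv_module_forward(model, X, training = FALSE)$out
  if (single) array(out[1L, , ], dim(out)[2:3]) else out
}

#' Transformer-encoder output for a token sequence
#'
#' Applies the `L` post-norm encoder layers to conv features `S`. Inference
#' mode (dropout off); deterministic. Optionally returns every layer's
#' attention-weight arrays (`Tc x Tc x h` per trial), whose rows are
#' non-negative and sum to one.
#'
#' @param model a `ctnet_model`.
#' @param S a `Tc x d` matrix (or `B x Tc x d` array) of conv features.
#' @param return_attention also return attention weights.
#' @return `E`, same shape as `S`; if `return_attention`, a list
#'   `list(E, attention)`.
#' @export
encoder_forward <- function(model, S, return_attention = FALSE) {
  cfg <- model$config
  Tc <- token_length(cfg$T_samples, cfg$P1, cfg$P2)
  single <- is.matrix(S)
  if (single) S <- array(S, c(1L, dim(S)))
  d3 <- dim(S)
  if (d3[2L] != Tc || d3[3L] != cfg$d) {
    stop("S must be (", Tc, " x ", cfg$d, ") conv features")
  }
  B <- d3[1L]
  Xl <- matrix(S, B * Tc, cfg$d)
  attn <- vector("list", cfg$L)
  for (l in seq_len(cfg$L)) {
    st <- encoder_layer_forward(model$params$enc[[l]], Xl, cfg, B, Tc,
                                training = FALSE)
    attn[[l]] <- st$attn
    Xl <- st$out
  }
  E <- array(Xl, c(B, Tc, cfg$d))
  if (single) E <- array(E[1L, , ], c(Tc, cfg$d))
  if (return_attention) list(E = E, attention = attn) else E
}

#' Residual-fused classifier head
#'
#' Adds the conv features and encoder output elementwise, flattens the
#' `Tc x d` sum to a vector, and applies the single fully connected layer.
#' Inference mode (classifier dropout off). Passing `E = 0` classifies from
#' conv features alone (the no-Transformer ablation path).
#'
#' @param model a `ctnet_model`.
#' @param S conv features, `Tc x d` matrix or `B x Tc x d` array.
#' @param E encoder output of the same shape (or the scalar 0).
#' @return logits: length-`N` vector for a single trial, `B x N` matrix for a
#'   batch.
#' @export
classify <- function(model, S, E = 0) {
  cfg <- model$config
  single <- is.matrix(S)
  if (single) S <- array(S, c(1L, dim(S)))
  if (identical(E, 0)) E <- array(0, dim(S))
  if (is.matrix(E)) E <- array(E, c(1L, dim(E)))
  stopifnot(identical(dim(S), dim(E)))
  B <- dim(S)[1L]; Tc <- dim(S)[2L]
  Fl <- matrix(array(S + E, c(B, Tc, cfg$d)), B, Tc * cfg$d)
  logits <- sweep(Fl %*% model$params$clf$W, 2L, model$params$clf$b, `+`)
  if (single) drop(logits) else logits
}

#' Forward pass: class logits and probabilities
#'
#' Full inference pass (conv module, encoder, classifier) in evaluation mode.
#'
#' @param model a `ctnet_model`.
#' @param x a `C x T` matrix, `B x C x T` array, or `trial_set`.
#' @return list with `logits` and softmax `probs` (`B x N` matrices).
#' @export
model_forward <- function(model, x) {
  if (inherits(x, "trial_set")) x <- x$data
  fw <- ctnet_full_forward(model, x, training = FALSE)
  list(logits = fw$logits, probs = softmax_rows(fw$logits))
}

#' Predicted class labels for a trial_set
#'
#' @param model a `ctnet_model`.
#' @param ts a `trial_set` (or bare array).
#' @return integer vector of 0-based predicted labels.
#' @export
predict_labels <- function(model, ts) {
  pr <- model_forward(model, ts)$probs
  max.col(pr, ties.method = "first") - 1L
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a serialized archive holding the architecture config,
#' all trainable parameters, batch-norm running statistics and a version tag.
#'
#' @param model a `ctnet_model`. @param path file path.
#' @return `path` (save) or the restored `ctnet_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ctnet_model"))
  saveRDS(list(format = "ctnet-checkpoint", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt checkpoint: ", conditionMessage(e)))
  if (!identical(obj$format, "ctnet-checkpoint")) {
    stop("corrupt checkpoint: field `format` missing or wrong")
  }
  obj$model
}
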