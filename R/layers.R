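# Neural-network primitives: forward and analytic backward passes.
#
# All layers operate on plain numeric arrays/matrices so that everything runs
# through BLAS. Convolutions use the cross-correlation convention of the
# deep-learning frameworks, with 'same' zero padding on the time axis
# (pad_left = floor((K-1)/2)). Each *_forward returns list(out, cache); each
# *_backward takes the upstream gradient plus the cache and returns the input
# gradient and any parameter gradients. Correctness of every backward pass is
# pinned by a central finite-difference test over the whole model.

IM2COL_CHUNK <- 2e7  # max doubles per im2col block (~160 MB)

#' Gaussian Error Linear Unit (exact form)
#'
#' `gelu(x) = x * Phi(x)` with `Phi` the standard-normal CDF computed via the
#' error function — the exact definition, not the tanh approximation.
#'
#' @param x numeric vector/array.
#' @return `x * pnorm(x)`, same shape as `x`.
#' @export
gelu <- function(x) x * stats::pnorm(x)

gelu_backward <- function(x, dy) dy * (stats::pnorm(x) + x * stats::dnorm(x))

elu_forward <- function(x) {
  y <- x
  neg <- x < 0
  y[neg] <- exp(x[neg]) - 1
  y
}
elu_backward <- function(x, y, dy) {
  g <- dy
  neg <- x < 0
  g[neg] <- dy[neg] * (y[neg] + 1)
  g
}

# ---- 1-d convolution over the time axis ------------------------------------
# X: (R, T, Min) array of R independent rows; W: (K, Min, Mout).
# Y[r,t,o] = sum_{m,k} Xpad[r, t+k-1, m] * W[k,m,o]; no bias (BN follows).

conv1d_pad <- function(X, K) {
  d <- dim(X); pl <- (K - 1L) %/% 2L
  Xp <- array(0, c(d[1L], d[2L] + K - 1L, d[3L]))
  Xp[, pl + seq_len(d[2L]), ] <- X
  Xp
}

conv1d_im2col <- function(Xp, rows, T_len, K, Min) {
  # columns ordered k fastest within m, matching matrix(W, K*Min, Mout)
  all_rows <- length(rows) == dim(Xp)[1L]
  Z <- matrix(0, length(rows) * T_len, K * Min)
  for (m in seq_len(Min)) {
    for (k in seq_len(K)) {
      Z[, (m - 1L) * K + k] <-
        if (all_rows) Xp[, k:(k + T_len - 1L), m]        # contiguous slice
        else Xp[rows, k:(k + T_len - 1L), m]
    }
  }
  Z
}

conv1d_same_forward <- function(X, W) {
  dX <- dim(X); R <- dX[1L]; T_len <- dX[2L]; Min <- dX[3L]
  K <- dim(W)[1L]; Mout <- dim(W)[3L]
  Xp <- conv1d_pad(X, K)
  W2 <- matrix(W, K * Min, Mout)
  Y <- array(0, c(R, T_len, Mout))
  chunk <- max(1L, as.integer(IM2COL_CHUNK %/% (as.double(T_len) * K * Min)))
  Zkeep <- NULL
  if (chunk >= R) {                # single chunk: no row-subset copies
    Zkeep <- conv1d_im2col(Xp, seq_len(R), T_len, K, Min)
    Y <- Zkeep %*% W2
    dim(Y) <- c(R, T_len, Mout)
  } else {
    for (start in seq(1L, R, by = chunk)) {
      rows <- start:min(R, start + chunk - 1L)
      Z <- conv1d_im2col(Xp, rows, T_len, K, Min)
      Y[rows, , ] <- array(Z %*% W2, c(length(rows), T_len, Mout))
    }
  }
  list(out = Y, cache = list(Xp = Xp, W = W, R = R, T_len = T_len,
                             Min = Min, K = K, Mout = Mout, Z = Zkeep))
}

conv1d_same_backward <- function(dY, cache, need_dx = TRUE) {
  R <- cache$R; T_len <- cache$T_len; Min <- cache$Min
  K <- cache$K; Mout <- cache$Mout
  W2 <- matrix(cache$W, K * Min, Mout)
  dW2 <- matrix(0, K * Min, Mout)
  dXp <- if (need_dx) array(0, dim(cache$Xp)) else NULL
  chunk <- max(1L, as.integer(IM2COL_CHUNK %/% (as.double(T_len) * K * Min)))
  single <- chunk >= R
  for (start in seq(1L, R, by = chunk)) {
    rows <- start:min(R, start + chunk - 1L)
    Z <- if (!is.null(cache$Z) && single) cache$Z
         else conv1d_im2col(cache$Xp, rows, T_len, K, Min)
    dYr <- if (single) dY else dY[rows, , , drop = FALSE]
    dim(dYr) <- c(length(rows) * T_len, Mout)
    dW2 <- dW2 + crossprod(Z, dYr)
    if (need_dx) {
      dZ <- dYr %*% t(W2)
      all_rows <- length(rows) == R
      for (m in seq_len(Min)) {
        for (k in seq_len(K)) {
          span <- k:(k + T_len - 1L)
          add <- matrix(dZ[, (m - 1L) * K + k], length(rows), T_len)
          if (all_rows) dXp[, span, m] <- dXp[, span, m] + add
          else dXp[rows, span, m] <- dXp[rows, span, m] + add
        }
      }
    }
  }
  dX <- NULL
  if (need_dx) {
    pl <- (K - 1L) %/% 2L
    dX <- dXp[, pl + seq_len(T_len), , drop = FALSE]
  }
  list(dX = dX, dW = array(dW2, dim(cache$W)))
}

# ---- depthwise spatial filter ----------------------------------------------
# X: (B*C, T, F1) with rows grouped channel-major (row = b + (c-1)*B);
# W: (C, F1, D). Output (B, T, F1*D), map index m = (f-1)*D + d.

depthwise_forward <- function(X, W, B) {
  C <- dim(W)[1L]; F1 <- dim(W)[2L]; D <- dim(W)[3L]
  T_len <- dim(X)[2L]
  Y <- array(0, c(B, T_len, F1 * D))
  for (f in seq_len(F1)) {
    for (dd in seq_len(D)) {
      acc <- matrix(0, B, T_len)
      for (c in seq_len(C)) {
        rows <- (c - 1L) * B + seq_len(B)
        acc <- acc + W[c, f, dd] * X[rows, , f]
      }
      Y[, , (f - 1L) * D + dd] <- acc
    }
  }
  list(out = Y, cache = list(X = X, W = W, B = B))
}

depthwise_backward <- function(dY, cache) {
  W <- cache$W; X <- cache$X; B <- cache$B
  C <- dim(W)[1L]; F1 <- dim(W)[2L]; D <- dim(W)[3L]
  dW <- array(0, dim(W))
  dX <- array(0, dim(X))
  for (f in seq_len(F1)) {
    for (dd in seq_len(D)) {
      dYm <- dY[, , (f - 1L) * D + dd]
      for (c in seq_len(C)) {
        rows <- (c - 1L) * B + seq_len(B)
        dW[c, f, dd] <- sum(X[rows, , f] * dYm)
        dX[rows, , f] <- dX[rows, , f] + W[c, f, dd] * dYm
      }
    }
  }
  list(dX = dX, dW = dW)
}

# ---- batch normalization (per feature map) ---------------------------------
# X: (R, T, M); normalizes each map m over all R*T entries. Running stats are
# updated with momentum during training (unbiased variance, framework
# convention) and used verbatim in evaluation mode.

batchnorm_forward <- function(X, gamma, beta, running, training,
                              momentum = 0.1, eps = 1e-5) {
  d <- dim(X); M <- d[3L]; n <- d[1L] * d[2L]
  dim(X) <- c(n, M)
  xhat <- X; Y <- X          # column-wise in place to avoid big temporaries
  if (training) {
    mu <- colMeans(X)
    var_b <- numeric(M)
    for (j in seq_len(M)) {
      xc <- X[, j] - mu[j]
      var_b[j] <- mean(xc * xc)
      xhat[, j] <- xc / sqrt(var_b[j] + eps)
      Y[, j] <- gamma[j] * xhat[, j] + beta[j]
    }
    ivar <- 1 / sqrt(var_b + eps)
    var_u <- if (n > 1L) var_b * n / (n - 1L) else var_b
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * var_u
  } else {
    ivar <- 1 / sqrt(running$var + eps)
    for (j in seq_len(M)) {
      xhat[, j] <- (X[, j] - running$mean[j]) * ivar[j]
      Y[, j] <- gamma[j] * xhat[, j] + beta[j]
    }
  }
  dim(Y) <- d
  list(out = Y, running = running,
       cache = list(xhat = xhat, ivar = ivar, gamma = gamma, d = d,
                    training = training))
}

batchnorm_backward <- function(dY, cache) {
  d <- cache$d; n <- d[1L] * d[2L]; M <- d[3L]
  dim(dY) <- c(n, M)
  xhat <- cache$xhat
  dgamma <- numeric(M); dbeta <- numeric(M)
  dX <- dY
  gi <- cache$gamma * cache$ivar
  for (j in seq_len(M)) {
    dgamma[j] <- sum(dY[, j] * xhat[, j])
    dbeta[j] <- sum(dY[, j])
    if (cache$training) {
      # full backward through the batch statistics
      dX[, j] <- gi[j] * (dY[, j] - dbeta[j] / n - xhat[, j] * dgamma[j] / n)
    } else {
      dX[, j] <- gi[j] * dY[, j]
    }
  }
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- average pooling along time --------------------------------------------
# X: (R, T, M) -> (R, floor(T/P), M); trailing remainder samples are dropped,
# which is what gives token_length its floor arithmetic.

avgpool_forward <- function(X, P) {
  d <- dim(X); T1 <- d[2L] %/% P
  Y <- array(0, c(d[1L], T1, d[3L]))
  for (p in seq_len(P)) {
    cols <- seq.int(p, by = P, length.out = T1)
    Y <- Y + X[, cols, , drop = FALSE]
  }
  list(out = Y / P, cache = list(d = d, P = P, T1 = T1))
}

avgpool_backward <- function(dY, cache) {
  d <- cache$d; P <- cache$P; T1 <- cache$T1
  dX <- array(0, d)
  idx <- rep(seq_len(T1), each = P)
  for (m in seq_len(d[3L])) {
    dX[, seq_len(T1 * P), m] <- dY[, idx, m] / P
  }
  dX
}

# ---- dropout ----------------------------------------------------------------
# Inverted dropout; masks are drawn from the current RNG stream so a seeded
# fit is bit-reproducible. p = 0 or eval mode is the identity.

dropout_forward <- function(X, p, training) {
  if (!training || p == 0) return(list(out = X, cache = NULL))
  mask <- array((stats::runif(length(X)) >= p) / (1 - p), dim(X) %||% length(X))
  list(out = X * mask, cache = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- layer normalization (per token row) -----------------------------------
# X: (n, d) matrix; each row normalized over its d features.

layernorm_forward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  ivar <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * ivar
  Y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(out = Y, cache = list(xhat = xhat, ivar = ivar, gamma = gamma))
}

layernorm_backward <- function(dY, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, cache$gamma, `*`)
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$ivar
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- linear -----------------------------------------------------------------

linear_forward <- function(X, W, b) {
  list(out = sweep(X %*% W, 2L, b, `+`), cache = list(X = X, W = W))
}

linear_backward <- function(dY, cache) {
  list(dX = dY %*% t(cache$W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

# ---- softmax ----------------------------------------------------------------

softmax_rows <- function(X) {
  e <- exp(X - apply(X, 1L, max))
  e / rowSums(e)
}

# ---- multi-head scaled dot-product attention -------------------------------
# X: (B*Tc, d) token matrix, rows b + (t-1)*B. Heads live in column blocks of
# width d_k. Attention weights per (trial, head) are cached for backward and
# can be surfaced for inspection.

attention_forward <- function(X, p, B, Tc, h, d_k) {
  Q <- sweep(X %*% p$WQ, 2L, p$bQ, `+`)
  K <- sweep(X %*% p$WK, 2L, p$bK, `+`)
  V <- sweep(X %*% p$WV, 2L, p$bV, `+`)
  Z <- matrix(0, nrow(X), h * d_k)
  A <- array(0, c(Tc, Tc, h, B))
  sc <- 1 / sqrt(d_k)
  for (b in seq_len(B)) {
    rows <- b + (seq_len(Tc) - 1L) * B
    for (i in seq_len(h)) {
      cols <- (i - 1L) * d_k + seq_len(d_k)
      Ab <- softmax_rows(Q[rows, cols, drop = FALSE] %*%
                           t(K[rows, cols, drop = FALSE]) * sc)
      A[, , i, b] <- Ab
      Z[rows, cols] <- Ab %*% V[rows, cols, drop = FALSE]
    }
  }
  out <- sweep(Z %*% p$WO, 2L, p$bO, `+`)
  list(out = out, attn = A,
       cache = list(X = X, Q = Q, K = K, V = V, Z = Z, A = A, p = p,
                    B = B, Tc = Tc, h = h, d_k = d_k))
}

attention_backward <- function(dY, cache) {
  p <- cache$p; B <- cache$B; Tc <- cache$Tc
  h <- cache$h; d_k <- cache$d_k
  sc <- 1 / sqrt(d_k)
  dWO <- crossprod(cache$Z, dY)
  dbO <- colSums(dY)
  dZ <- dY %*% t(p$WO)
  dQ <- matrix(0, nrow(dZ), h * d_k)
  dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- b + (seq_len(Tc) - 1L) * B
    for (i in seq_len(h)) {
      cols <- (i - 1L) * d_k + seq_len(d_k)
      Ab <- cache$A[, , i, b]
      Vb <- cache$V[rows, cols, drop = FALSE]
      dZb <- dZ[rows, cols, drop = FALSE]
      dA <- dZb %*% t(Vb)
      dV[rows, cols] <- crossprod(Ab, dZb)
      dS <- Ab * (dA - rowSums(dA * Ab))   # softmax rows backward
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] * sc
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) * sc
    }
  }
  X <- cache$X
  list(dX = dQ %*% t(p$WQ) + dK %*% t(p$WK) + dV %*% t(p$WV),
       dWQ = crossprod(X, dQ), dbQ = colSums(dQ),
       dWK = crossprod(X, dK), dbK = colSums(dK),
       dWV = crossprod(X, dV), dbV = colSums(dV),
       dWO = dWO, dbO = dbO)
}
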