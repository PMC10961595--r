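# Neural-net primitives: 1-D convolution (im2col + GEMM), LSTM, dense,
# softmax, and Adam. All forward functions return caches sufficient for the
# matching backward pass; everything is plain double matrices so BLAS does
# the heavy lifting.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Keras-style "same" padding for stride-s convolution: L_out = ceil(L/s).
pad_same <- function(L, K, s) {
  L_out <- ceiling(L / s)
  p <- max(0L, (L_out - 1L) * s + K - L)
  list(pl = p %/% 2L, pr = p - p %/% 2L, L_out = as.integer(L_out))
}

# Left-only padding: causal convolution, L_out = L (stride 1).
pad_causal <- function(L, K, s) {
  stopifnot(s == 1)
  list(pl = K - 1L, pr = 0L, L_out = as.integer(L))
}

# x: L x C input. W: (C*K) x F with column layout (c-1)*K + k. Returns
# post-ReLU output (L_out x F) and a cache for the backward pass.
conv1d_fwd <- function(x, W, b, K, s, pad = c("same", "causal"),
                       relu = TRUE, with_cache = TRUE) {
  pad <- match.arg(pad)
  L <- nrow(x); C <- ncol(x)
  pp <- if (pad == "same") pad_same(L, K, s) else pad_causal(L, K, s)
  Lp <- L + pp$pl + pp$pr
  Xp <- matrix(0, Lp, C)
  Xp[(pp$pl + 1):(pp$pl + L), ] <- x
  idx <- outer(seq_len(pp$L_out) - 1L, seq_len(K), function(j, k) j * s + k)
  A <- Xp[as.vector(idx), , drop = FALSE]       # (L_out*K) x C, j fastest
  dim(A) <- c(pp$L_out, K * C)                  # columns: (c-1)*K + k
  pre <- A %*% W
  pre <- pre + rep(b, each = pp$L_out)
  out <- if (relu) pmax(pre, 0) else pre
  cache <- if (with_cache) {
    list(Z = A, mask = if (relu) pre > 0 else NULL, idx = idx,
         L = L, Lp = Lp, pl = pp$pl, C = C, K = K)
  }
  list(out = out, cache = cache)
}

conv1d_bwd <- function(dout, cache, W) {
  dpre <- if (is.null(cache$mask)) dout else dout * cache$mask
  dW <- crossprod(cache$Z, dpre)
  db <- colSums(dpre)
  dZ <- tcrossprod(dpre, W)                           # L_out x (K*C)
  L_out <- nrow(dZ)
  dim(dZ) <- c(L_out, cache$K, cache$C)
  dXp <- matrix(0, cache$Lp, cache$C)
  for (k in seq_len(cache$K)) {
    rows <- cache$idx[, k]
    dXp[rows, ] <- dXp[rows, ] + matrix(dZ[, k, ], L_out, cache$C)
  }
  dx <- dXp[(cache$pl + 1):(cache$pl + cache$L), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# X: array [B, D, Tmax]; W: D x 4H, U: H x 4H, b: 4H (gate order i, f, g, o).
# Padded timesteps (zero inputs beyond a sequence's length) are harmless:
# the recurrence is causal, and the backward pass only receives gradients at
# valid (masked-in) timesteps.
lstm_fwd <- function(X, W, U, b, with_cache = TRUE) {
  B <- dim(X)[1]; D <- dim(X)[2]; Tm <- dim(X)[3]
  H <- ncol(U) / 4L
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Harr <- array(0, c(B, H, Tm))
  cache <- if (with_cache) {
    list(i = array(0, c(B, H, Tm)), f = array(0, c(B, H, Tm)),
         g = array(0, c(B, H, Tm)), o = array(0, c(B, H, Tm)),
         c = array(0, c(B, H, Tm)), tc = array(0, c(B, H, Tm)))
  }
  bmat <- rep(b, each = B)
  for (t in seq_len(Tm)) {
    Xt <- matrix(X[, , t], B, D)
    A <- Xt %*% W + h %*% U + bmat
    i_ <- sigmoid(A[, 1:H, drop = FALSE])
    f_ <- sigmoid(A[, (H + 1):(2 * H), drop = FALSE])
    g_ <- tanh(A[, (2 * H + 1):(3 * H), drop = FALSE])
    o_ <- sigmoid(A[, (3 * H + 1):(4 * H), drop = FALSE])
    cc_new <- f_ * cc + i_ * g_
    tc <- tanh(cc_new)
    h <- o_ * tc
    Harr[, , t] <- h
    if (with_cache) {
      cache$i[, , t] <- i_; cache$f[, , t] <- f_
      cache$g[, , t] <- g_; cache$o[, , t] <- o_
      cache$c[, , t] <- cc_new; cache$tc[, , t] <- tc
    }
    cc <- cc_new
  }
  list(H = Harr, cache = cache)
}

lstm_bwd <- function(dH, X, W, U, cache) {
  B <- dim(X)[1]; D <- dim(X)[2]; Tm <- dim(X)[3]
  H <- ncol(U) / 4L
  dX <- array(0, c(B, D, Tm))
  dW <- matrix(0, D, 4 * H); dU <- matrix(0, H, 4 * H); db <- numeric(4 * H)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tm))) {
    i_ <- matrix(cache$i[, , t], B, H); f_ <- matrix(cache$f[, , t], B, H)
    g_ <- matrix(cache$g[, , t], B, H); o_ <- matrix(cache$o[, , t], B, H)
    tc <- matrix(cache$tc[, , t], B, H)
    cprev <- if (t > 1) matrix(cache$c[, , t - 1], B, H) else matrix(0, B, H)
    hprev <- if (t > 1) matrix(cache$tc[, , t - 1] * cache$o[, , t - 1], B, H)
             else matrix(0, B, H)
    dh <- matrix(dH[, , t], B, H) + dh_next
    do_ <- dh * tc
    dc <- dc_next + dh * o_ * (1 - tc^2)
    di <- dc * g_
    df <- dc * cprev
    dg <- dc * i_
    dA <- cbind(di * i_ * (1 - i_), df * f_ * (1 - f_),
                dg * (1 - g_^2), do_ * o_ * (1 - o_))
    Xt <- matrix(X[, , t], B, D)
    dX[, , t] <- tcrossprod(dA, W)
    dW <- dW + crossprod(Xt, dA)
    dU <- dU + crossprod(hprev, dA)
    db <- db + colSums(dA)
    dh_next <- tcrossprod(dA, U)
    dc_next <- dc * f_
  }
  list(dX = dX, dW = dW, dU = dU, db = db)
}

# Row-wise log-softmax / softmax with the usual max-shift stabilization.
log_softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  s <- x - m
  s - log(rowSums(exp(s)))
}

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

# Given softmax outputs P and gradient dP w.r.t. P, gradient w.r.t. logits.
softmax_bwd_rows <- function(P, dP) {
  P * (dP - rowSums(dP * P))
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip_norm = 5) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gnorm) && gnorm > clip_norm) {
    grads <- lapply(grads, function(g) g * (clip_norm / gnorm))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
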