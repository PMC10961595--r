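#' Model configuration
#'
#' Hyper-parameters of the concept-bottleneck recognizer. The architecture
#' is: per-sensor 1-D convolution (64 filters, kernel 16, stride 2, ReLU),
#' cross-sensor 1-D convolution (128 filters, kernel 16, stride 2, ReLU), a
#' bidirectional LSTM (128 units per direction), a time-distributed dense
#' layer with softmax over the M concepts plus the CTC blank, and a
#' classifier consisting of one causal temporal convolution (64 filters,
#' kernel 8, stride 1, ReLU) over the bottleneck probabilities followed by
#' global average pooling and a dense softmax over the L classes. The
#' classifier sees only the M+1 bottleneck channels, so all class
#' information must pass through the concept bottleneck.
#'
#' The two stride-2 convolutions shrink the timebase by 4: an input of
#' length T yields `ceiling(ceiling(T/2)/2)` concept rows.
#'
#' @param concepts character vector of M concept identifiers.
#' @param classes character vector of L class identifiers.
#' @param n_channels number of sensor channels S.
#' @param conv1_filters,conv1_kernel,conv1_stride per-sensor convolution.
#' @param conv2_filters,conv2_kernel,conv2_stride cross-sensor convolution.
#' @param lstm_units LSTM units per direction.
#' @param clf_filters,clf_kernel classifier temporal convolution.
#' @param beta weight of the classification loss in the joint objective
#'   `L = beta * L_Y + (1 - beta) * L_C`; 0.5 gives both terms equal
#'   importance.
#' @param lr,batch_size,epochs,patience Adam learning rate, mini-batch size,
#'   maximum epochs, and early-stopping patience (epochs without validation
#'   macro-F1 improvement).
#' @param beam_width beam width used whenever concept sequences are decoded.
#' @param seed integer seed controlling initialization and batch shuffling.
#' @return object of class `xchar_config`.
#' @export
xchar_config <- function(concepts, classes, n_channels = 3L,
                         conv1_filters = 64L, conv1_kernel = 16L,
                         conv1_stride = 2L,
                         conv2_filters = 128L, conv2_kernel = 16L,
                         conv2_stride = 2L,
                         lstm_units = 128L,
                         clf_filters = 64L, clf_kernel = 8L,
                         beta = 0.5, lr = 1e-3, batch_size = 32L,
                         epochs = 30L, patience = 10L,
                         beam_width = 25L, seed = 1L) {
  stopifnot(length(concepts) >= 1, length(classes) >= 2, n_channels >= 1,
            conv1_filters >= 1, conv2_filters >= 1, lstm_units >= 1,
            clf_filters >= 1, beta >= 0, beta <= 1, lr > 0,
            batch_size >= 1, epochs >= 1, beam_width >= 1)
  structure(list(
    concepts = as.character(concepts), classes = as.character(classes),
    n_channels = as.integer(n_channels),
    conv1_filters = as.integer(conv1_filters),
    conv1_kernel = as.integer(conv1_kernel),
    conv1_stride = as.integer(conv1_stride),
    conv2_filters = as.integer(conv2_filters),
    conv2_kernel = as.integer(conv2_kernel),
    conv2_stride = as.integer(conv2_stride),
    lstm_units = as.integer(lstm_units),
    clf_filters = as.integer(clf_filters),
    clf_kernel = as.integer(clf_kernel),
    beta = beta, lr = lr, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), patience = as.integer(patience),
    beam_width = as.integer(beam_width), seed = as.integer(seed)
  ), class = "xchar_config")
}

#' Output timebase length for an input of length T
#'
#' @param T_in input length in samples.
#' @param config an [xchar_config()].
#' @return integer T' after the two strided convolutions.
#' @export
t_prime_len <- function(T_in, config) {
  as.integer(ceiling(ceiling(T_in / config$conv1_stride) / config$conv2_stride))
}

min_input_len <- function(config) config$conv1_stride * config$conv2_stride

#' Build an untrained model
#'
#' Initializes all parameters (Glorot-uniform weights, zero biases with the
#' LSTM forget gate biased to 1) deterministically from `config$seed`.
#'
#' @param config an [xchar_config()].
#' @return object of class `xchar_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "xchar_config"))
  S <- config$n_channels
  M1 <- length(config$concepts) + 1L
  L <- length(config$classes)
  H <- config$lstm_units
  D <- config$conv2_filters
  params <- list()
  with_seed(config$seed, {
    for (s in seq_len(S)) {
      params[[paste0("conv1_W_", s)]] <-
        glorot(config$conv1_kernel, config$conv1_filters)
      params[[paste0("conv1_b_", s)]] <- numeric(config$conv1_filters)
    }
    params$conv2_W <- glorot(S * config$conv1_filters * config$conv2_kernel,
                             config$conv2_filters)
    params$conv2_b <- numeric(config$conv2_filters)
    for (dir in c("f", "b")) {
      params[[paste0("lstm_W_", dir)]] <- glorot(D, 4L * H)
      params[[paste0("lstm_U_", dir)]] <- glorot(H, 4L * H)
      bias <- numeric(4L * H)
      bias[(H + 1):(2 * H)] <- 1  # forget-gate bias
      params[[paste0("lstm_b_", dir)]] <- bias
    }
    params$dense_W <- glorot(2L * H, M1)
    params$dense_b <- numeric(M1)
    params$clf_W <- glorot(M1 * config$clf_kernel, config$clf_filters)
    params$clf_b <- numeric(config$clf_filters)
    params$out_W <- glorot(config$clf_filters, L)
    params$out_b <- numeric(L)
  })
  structure(list(config = config, params = params, norm = NULL,
                 history = NULL),
            class = "xchar_model")
}

#' @export
print.xchar_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat("<xchar_model> ", length(x$config$concepts), " concepts, ",
      length(x$config$classes), " classes, ",
      format(n_par, big.mark = ","), " parameters",
      if (is.null(x$norm)) " (untrained)" else " (trained)", "\n", sep = "")
  invisible(x)
}

check_window_shape <- function(model, values) {
  if (nrow(values) != model$config$n_channels) {
    stop("expected ", model$config$n_channels, " channels, got ",
         nrow(values), call. = FALSE)
  }
  if (ncol(values) < min_input_len(model$config)) {
    stop("input too short for the convolution stack: need at least ",
         min_input_len(model$config), " samples, got ", ncol(values),
         call. = FALSE)
  }
}

normalize_values <- function(model, values) {
  if (is.null(model$norm)) return(values)
  (values - model$norm$mean) / model$norm$sd
}

# Forward pass over a list of S x T matrices (already raw; normalization is
# applied here). Returns per-window concept log-probability matrices, class
# log-probabilities (B x L), and, when with_cache, every intermediate needed
# by model_backward().
model_forward <- function(model, xs, with_cache = FALSE) {
  cfg <- model$config
  S <- cfg$n_channels
  M1 <- length(cfg$concepts) + 1L
  H <- cfg$lstm_units
  D <- cfg$conv2_filters
  B <- length(xs)
  p <- model$params

  conv_caches <- vector("list", B)
  F_list <- vector("list", B)
  t2 <- integer(B)
  for (i in seq_len(B)) {
    check_window_shape(model, xs[[i]])
    x <- t(normalize_values(model, xs[[i]]))           # T x S
    sens <- vector("list", S)
    c1 <- vector("list", S)
    for (s in seq_len(S)) {
      r <- conv1d_fwd(x[, s, drop = FALSE],
                      p[[paste0("conv1_W_", s)]], p[[paste0("conv1_b_", s)]],
                      cfg$conv1_kernel, cfg$conv1_stride, "same",
                      with_cache = with_cache)
      sens[[s]] <- r$out
      c1[[s]] <- r$cache
    }
    H1 <- do.call(cbind, sens)                          # T1 x (S*f1)
    r2 <- conv1d_fwd(H1, p$conv2_W, p$conv2_b,
                     cfg$conv2_kernel, cfg$conv2_stride, "same",
                     with_cache = with_cache)
    F_list[[i]] <- r2$out                               # T2 x D
    t2[i] <- nrow(r2$out)
    if (with_cache) conv_caches[[i]] <- list(c1 = c1, c2 = r2$cache)
  }
  t2max <- max(t2)
  Xf <- array(0, c(B, D, t2max))
  Xr <- array(0, c(B, D, t2max))
  for (i in seq_len(B)) {
    Fi <- F_list[[i]]
    Xf[i, , seq_len(t2[i])] <- t(Fi)
    Xr[i, , seq_len(t2[i])] <- t(Fi[t2[i]:1, , drop = FALSE])
  }
  lf <- lstm_fwd(Xf, p$lstm_W_f, p$lstm_U_f, p$lstm_b_f, with_cache)
  lb <- lstm_fwd(Xr, p$lstm_W_b, p$lstm_U_b, p$lstm_b_b, with_cache)

  # stack valid (window, timestep) rows: forward states, then un-reversed
  # backward states
  N <- sum(t2)
  R <- matrix(0, N, 2L * H)
  off <- c(0L, cumsum(t2))
  for (i in seq_len(B)) {
    rows <- (off[i] + 1):(off[i] + t2[i])
    Hf_i <- t(matrix(lf$H[i, , seq_len(t2[i])], H))     # T2 x H
    Hb_i <- t(matrix(lb$H[i, , seq_len(t2[i])], H))[t2[i]:1, , drop = FALSE]
    R[rows, ] <- cbind(Hf_i, Hb_i)
  }
  logits <- R %*% p$dense_W + rep(p$dense_b, each = N)
  logP <- log_softmax_rows(logits)
  P <- exp(logP)

  clf_caches <- vector("list", B)
  Q <- matrix(0, B, cfg$clf_filters)
  for (i in seq_len(B)) {
    rows <- (off[i] + 1):(off[i] + t2[i])
    Pi <- P[rows, , drop = FALSE]
    rc <- conv1d_fwd(Pi, p$clf_W, p$clf_b, cfg$clf_kernel, 1L, "causal",
                     with_cache = with_cache)
    Q[i, ] <- colMeans(rc$out)
    if (with_cache) clf_caches[[i]] <- rc$cache
  }
  class_logits <- Q %*% p$out_W + rep(p$out_b, each = B)
  class_logP <- log_softmax_rows(class_logits)

  out <- list(t2 = t2, off = off, logP = logP, P = P,
              class_logP = class_logP, class_probs = exp(class_logP))
  if (with_cache) {
    out$cache <- list(conv = conv_caches, lf = lf, lb = lb, Xf = Xf, Xr = Xr,
                      R = R, Q = Q, clf = clf_caches, B = B, t2max = t2max)
  }
  out
}

# Joint loss and parameter gradients for one mini-batch.
# targets: list of concept character vectors; y_idx: class indices.
model_backward <- function(model, xs, targets, y_idx, fwd) {
  cfg <- model$config
  S <- cfg$n_channels
  M1 <- length(cfg$concepts) + 1L
  H <- cfg$lstm_units
  D <- cfg$conv2_filters
  B <- length(xs)
  p <- model$params
  beta <- cfg$beta
  t2 <- fwd$t2; off <- fwd$off
  cache <- fwd$cache

  # classification loss and gradient
  ce <- -fwd$class_logP[cbind(seq_len(B), y_idx)]
  L_Y <- mean(ce)
  dclass_logits <- fwd$class_probs
  dclass_logits[cbind(seq_len(B), y_idx)] <-
    dclass_logits[cbind(seq_len(B), y_idx)] - 1
  dclass_logits <- dclass_logits * (beta / B)

  grads <- lapply(p, function(x) x * 0)
  grads$out_W <- crossprod(cache$Q, dclass_logits)
  grads$out_b <- colSums(dclass_logits)
  dQ <- dclass_logits %*% t(p$out_W)

  # CTC loss per window + classifier gradient w.r.t. bottleneck probabilities
  ctc_losses <- numeric(B)
  dlogits_rows <- matrix(0, nrow(fwd$P), M1)
  for (i in seq_len(B)) {
    rows <- (off[i] + 1):(off[i] + t2[i])
    Pi <- fwd$P[rows, , drop = FALSE]
    # classifier branch
    dHc <- matrix(dQ[i, ] / t2[i], t2[i], cfg$clf_filters, byrow = TRUE)
    cb <- conv1d_bwd(dHc, cache$clf[[i]], p$clf_W)
    grads$clf_W <- grads$clf_W + cb$dW
    grads$clf_b <- grads$clf_b + cb$db
    dPi_clf <- cb$dx
    # CTC branch (gradient w.r.t. bottleneck logits is P - gamma)
    idx <- match(targets[[i]], cfg$concepts)
    fb <- ctc_forward_backward(fwd$logP[rows, , drop = FALSE], idx, M1)
    ctc_losses[i] <- fb$loss
    dlogits_rows[rows, ] <-
      ((1 - beta) / B) * (Pi - fb$gamma) +
      softmax_bwd_rows(Pi, dPi_clf)
  }
  L_C <- mean(ctc_losses)

  # bottleneck dense
  grads$dense_W <- crossprod(cache$R, dlogits_rows)
  grads$dense_b <- colSums(dlogits_rows)
  dR <- dlogits_rows %*% t(p$dense_W)

  # scatter into LSTM gradient arrays (backward direction re-reversed)
  dHf <- array(0, c(B, H, cache$t2max))
  dHb <- array(0, c(B, H, cache$t2max))
  for (i in seq_len(B)) {
    rows <- (off[i] + 1):(off[i] + t2[i])
    dHf[i, , seq_len(t2[i])] <- t(dR[rows, 1:H, drop = FALSE])
    dHb[i, , seq_len(t2[i])] <-
      t(dR[rev(rows), (H + 1):(2 * H), drop = FALSE])
  }
  bf <- lstm_bwd(dHf, cache$Xf, p$lstm_W_f, p$lstm_U_f, cache$lf$cache)
  bb <- lstm_bwd(dHb, cache$Xr, p$lstm_W_b, p$lstm_U_b, cache$lb$cache)
  grads$lstm_W_f <- bf$dW; grads$lstm_U_f <- bf$dU; grads$lstm_b_f <- bf$db
  grads$lstm_W_b <- bb$dW; grads$lstm_U_b <- bb$dU; grads$lstm_b_b <- bb$db

  # through the convolution stack, window by window
  for (i in seq_len(B)) {
    dFi <- t(matrix(bf$dX[i, , seq_len(t2[i])], D)) +
      t(matrix(bb$dX[i, , seq_len(t2[i])], D))[t2[i]:1, , drop = FALSE]
    c2 <- conv1d_bwd(dFi, cache$conv[[i]]$c2, p$conv2_W)
    grads$conv2_W <- grads$conv2_W + c2$dW
    grads$conv2_b <- grads$conv2_b + c2$db
    f1 <- cfg$conv1_filters
    for (s in seq_len(S)) {
      cols <- ((s - 1) * f1 + 1):(s * f1)
      c1 <- conv1d_bwd(c2$dx[, cols, drop = FALSE],
                       cache$conv[[i]]$c1[[s]], p[[paste0("conv1_W_", s)]])
      grads[[paste0("conv1_W_", s)]] <-
        grads[[paste0("conv1_W_", s)]] + c1$dW
      grads[[paste0("conv1_b_", s)]] <-
        grads[[paste0("conv1_b_", s)]] + c1$db
    }
  }
  list(loss = beta * L_Y + (1 - beta) * L_C, class_loss = L_Y,
       concept_loss = L_C, grads = grads)
}
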