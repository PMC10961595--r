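#' Train the recognizer end to end
#'
#' Minimizes the joint objective `L = beta * L_Y + (1 - beta) * L_C`, where
#' `L_Y` is the categorical cross-entropy of the class head and `L_C` is the
#' CTC loss of the concept bottleneck against the weak (timestamp-free)
#' concept-sequence labels, with Adam on mini-batches. Per-channel z-score
#' normalization is fitted on the training windows and stored with the
#' model. After every epoch the validation macro-F1 and mean concept edit
#' distance are logged; the parameters with the best validation macro-F1 are
#' kept (ties resolved by lower edit distance). Training stops early when
#' the validation macro-F1 has not improved for `config$patience` epochs.
#'
#' @param model an [build_model()] result.
#' @param train_windows list of [sensor_window()] for training.
#' @param val_windows optional validation windows (default: none; the last
#'   epoch's parameters are kept).
#' @param epochs,batch_size,verbose overrides of the config / reporting.
#' @return the trained model, with `$history` a data.frame with one row per
#'   epoch: `epoch`, `loss`, `concept_loss`, `class_loss`, `val_macro_f1`,
#'   `val_edit_distance`.
#' @export
train_model <- function(model, train_windows, val_windows = NULL,
                        epochs = model$config$epochs,
                        batch_size = model$config$batch_size,
                        verbose = FALSE) {
  stopifnot(inherits(model, "xchar_model"), length(train_windows) >= 1)
  cfg <- model$config
  check_dataset_compat(cfg, train_windows)
  if (!is.null(val_windows)) check_dataset_compat(cfg, val_windows)

  # fit per-channel z-score normalization on the training data
  all_vals <- do.call(cbind, lapply(train_windows, function(w) w$values))
  mu <- rowMeans(all_vals)
  sd_ <- apply(all_vals, 1, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  model$norm <- list(mean = mu, sd = sd_)

  # every CTC target must be representable on its output timebase
  t2_all <- vapply(train_windows, function(w) t_prime_len(ncol(w$values), cfg),
                   integer(1))
  need <- vapply(train_windows, function(w) ctc_min_length(w$concepts),
                 integer(1))
  bad <- which(t2_all < need)
  if (length(bad) > 0) {
    stop("CTC-infeasible concept targets for window(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         ": target needs more output timesteps than the window provides",
         call. = FALSE)
  }

  xs <- lapply(train_windows, function(w) w$values)
  targets <- lapply(train_windows, function(w) w$concepts)
  y_idx <- match(vapply(train_windows, function(w) w$class_label,
                        character(1)), cfg$classes)

  opt <- adam_init(model$params)
  n <- length(xs)
  hist_rows <- vector("list", epochs)
  best <- list(f1 = -Inf, edit = Inf, params = model$params)
  stall <- 0L
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batch_starts <- seq(1, n, by = batch_size)
      tot <- c(loss = 0, concept = 0, class = 0)
      for (bs in batch_starts) {
        sel <- ord[bs:min(bs + batch_size - 1, n)]
        fwd <- model_forward(model, xs[sel], with_cache = TRUE)
        bwd <- model_backward(model, xs[sel], targets[sel], y_idx[sel], fwd)
        if (!is.finite(bwd$loss)) {
          stop("non-finite loss at epoch ", ep, " (batch starting ", bs,
               "); concept loss ", format(bwd$concept_loss),
               ", class loss ", format(bwd$class_loss), call. = FALSE)
        }
        upd <- adam_step(model$params, bwd$grads, opt, lr = cfg$lr)
        model$params <- upd$params
        opt <- upd$state
        w <- length(sel) / n
        tot <- tot + w * c(bwd$loss, bwd$concept_loss, bwd$class_loss)
      }
      val_f1 <- NA_real_
      val_edit <- NA_real_
      if (!is.null(val_windows)) {
        vm <- quick_val_metrics(model, val_windows)
        val_f1 <- vm$f1
        val_edit <- vm$edit
        better <- val_f1 > best$f1 ||
          (val_f1 == best$f1 && val_edit < best$edit)
        if (better) {
          best <- list(f1 = val_f1, edit = val_edit, params = model$params)
          stall <- 0L
        } else stall <- stall + 1L
      }
      hist_rows[[ep]] <- data.frame(
        epoch = ep, loss = tot[["loss"]], concept_loss = tot[["concept"]],
        class_loss = tot[["class"]], val_macro_f1 = val_f1,
        val_edit_distance = val_edit)
      if (verbose) {
        message(sprintf(
          "epoch %d  loss %.4f  (concept %.4f, class %.4f)  val F1 %s  val edit %s",
          ep, tot[["loss"]], tot[["concept"]], tot[["class"]],
          ifelse(is.na(val_f1), "-", sprintf("%.3f", val_f1)),
          ifelse(is.na(val_edit), "-", sprintf("%.3f", val_edit))))
      }
      # stop on perfect validation (nothing left to improve) or stall
      if (!is.null(val_windows) &&
          ((val_f1 == 1 && val_edit == 0) || stall >= cfg$patience)) break
    }
  })
  if (!is.null(val_windows) && is.finite(best$f1)) model$params <- best$params
  model$history <- do.call(rbind, hist_rows[!vapply(hist_rows, is.null,
                                                    logical(1))])
  model
}

check_dataset_compat <- function(cfg, windows) {
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (!w$class_label %in% cfg$classes) {
      stop("window ", i, " has class '", w$class_label,
           "' not in the model's classes", call. = FALSE)
    }
    unknown <- setdiff(w$concepts, cfg$concepts)
    if (length(unknown) > 0) {
      stop("window ", i, " labeled with concept(s) outside the alphabet: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Cheap per-epoch validation: batched forward, small-beam decoding.
quick_val_metrics <- function(model, windows, beam_width = 5L) {
  fwd <- model_forward(model, lapply(windows, function(w) w$values))
  pred_idx <- max.col(fwd$class_logP, ties.method = "first")
  truth <- vapply(windows, function(w) w$class_label, character(1))
  f1 <- macro_f1(truth, model$config$classes[pred_idx])
  edits <- vapply(seq_along(windows), function(i) {
    rows <- (fwd$off[i] + 1):(fwd$off[i] + fwd$t2[i])
    cm <- concept_matrix(fwd$P[rows, , drop = FALSE], model$config$concepts)
    dec <- beam_decode(cm, beam_width)$sequence
    levenshtein(dec, windows[[i]]$concepts)
  }, numeric(1))
  list(f1 = f1, edit = mean(edits))
}

#' Predict the complex activity of a sensor window
#'
#' @param object a trained `xchar_model`.
#' @param values numeric S x T matrix (raw, unnormalized).
#' @param ... unused.
#' @return list with `class_label` (argmax of the class probabilities; ties
#'   broken by the lowest class index), `class_probs` (named length-L
#'   vector) and `concept_matrix` (T' x (M+1) [concept_matrix()]).
#' @export
predict.xchar_model <- function(object, values, ...) {
  fwd <- model_forward(object, list(values))
  probs <- drop(fwd$class_probs)
  names(probs) <- object$config$classes
  cm <- concept_matrix(fwd$P, object$config$concepts)
  idx <- which.max(probs)  # first maximum = lowest class index on ties
  list(class_label = object$config$classes[idx],
       class_probs = probs,
       concept_matrix = cm)
}

#' Decode the concept sequence of a sensor window
#'
#' Runs the forward pass and prefix beam search on the bottleneck output.
#'
#' @param model trained `xchar_model`.
#' @param values S x T matrix.
#' @param beam_width beam width (default from the config).
#' @return as [beam_decode()].
#' @export
decode_concepts <- function(model, values,
                            beam_width = model$config$beam_width) {
  pred <- predict(model, values)
  beam_decode(pred$concept_matrix, beam_width)
}

#' Classify directly from a concept matrix
#'
#' Applies only the classifier head (causal temporal convolution, global
#' average pooling, dense softmax) to a given bottleneck matrix. Used to
#' probe bottleneck sufficiency: an idealized one-hot concept matrix built
#' from ground-truth segments should classify at least as well as the
#' model's own bottleneck output.
#'
#' @param model trained `xchar_model`.
#' @param cm T' x (M+1) matrix (concept columns then blank).
#' @return list with `class_label` and `class_probs`.
#' @export
predict_from_concepts <- function(model, cm) {
  cfg <- model$config
  p <- model$params
  rc <- conv1d_fwd(unclass(cm), p$clf_W, p$clf_b, cfg$clf_kernel, 1L,
                   "causal", with_cache = FALSE)
  q <- colMeans(rc$out)
  logits <- drop(q %*% p$out_W) + p$out_b
  probs <- exp(logits - max(logits))
  probs <- probs / sum(probs)
  names(probs) <- cfg$classes
  list(class_label = cfg$classes[which.max(probs)], class_probs = probs)
}

#' Fit the classifier module alone on given concept matrices
#'
#' Trains a fresh instance of the classifier head (causal temporal
#' convolution, global average pooling, dense softmax) by cross-entropy on
#' supplied bottleneck matrices. This probes bottleneck sufficiency
#' independently of the CTC-trained bottleneck's output style: the
#' CTC-trained bottleneck tends to be peaky (brief concept spikes amid
#' blanks), so a densely occupied idealized matrix is out of distribution
#' for the jointly trained head, and sufficiency must be assessed with a
#' head fitted to the idealized representation itself.
#'
#' @param config an [xchar_config()].
#' @param cms list of T' x (M+1) concept matrices.
#' @param labels class labels (one per matrix, from `config$classes`).
#' @param epochs full-batch Adam iterations per restart.
#' @param lr learning rate.
#' @param seed base initialization seed.
#' @param restarts independent initializations; the fit with the lowest
#'   final training loss is kept. Sufficiency is an existence question
#'   ("can this representation support classification?"), so the probe is
#'   entitled to its best optimization outcome; selection uses training
#'   loss only, never held-out data.
#' @return object of class `xchar_concept_classifier` with a `params` list;
#'   use [predict_concept_classifier()] for inference.
#' @export
fit_concept_classifier <- function(config, cms, labels, epochs = 600L,
                                   lr = 1e-2, seed = config$seed,
                                   restarts = 3L) {
  stopifnot(length(cms) == length(labels), length(cms) >= 1, restarts >= 1)
  M1 <- length(config$concepts) + 1L
  L <- length(config$classes)
  y_idx <- match(as.character(labels), config$classes)
  stopifnot(!anyNA(y_idx))
  n <- length(cms)

  fit_once <- function(init_seed) {
    params <- list()
    with_seed(init_seed, {
      params$clf_W <- glorot(M1 * config$clf_kernel, config$clf_filters)
      params$clf_b <- numeric(config$clf_filters)
      params$out_W <- glorot(config$clf_filters, L)
      params$out_b <- numeric(L)
    })
    opt <- adam_init(params)
    loss <- Inf
    for (ep in seq_len(epochs)) {
      grads <- lapply(params, function(x) x * 0)
      Q <- matrix(0, n, config$clf_filters)
      caches <- vector("list", n)
      for (i in seq_len(n)) {
        rc <- conv1d_fwd(unclass(cms[[i]]), params$clf_W, params$clf_b,
                         config$clf_kernel, 1L, "causal")
        Q[i, ] <- colMeans(rc$out)
        caches[[i]] <- rc$cache
      }
      logits <- Q %*% params$out_W + rep(params$out_b, each = n)
      logP <- log_softmax_rows(logits)
      loss <- -mean(logP[cbind(seq_len(n), y_idx)])
      dlogits <- (exp(logP) - diag(L)[y_idx, , drop = FALSE]) / n
      grads$out_W <- crossprod(Q, dlogits)
      grads$out_b <- colSums(dlogits)
      dQ <- tcrossprod(dlogits, params$out_W)
      for (i in seq_len(n)) {
        t2 <- nrow(cms[[i]])
        dHc <- matrix(dQ[i, ] / t2, t2, config$clf_filters, byrow = TRUE)
        cb <- conv1d_bwd(dHc, caches[[i]], params$clf_W)
        grads$clf_W <- grads$clf_W + cb$dW
        grads$clf_b <- grads$clf_b + cb$db
      }
      upd <- adam_step(params, grads, opt, lr = lr)
      params <- upd$params
      opt <- upd$state
    }
    list(params = params, loss = loss)
  }

  fits <- lapply(seq_len(restarts) - 1L, function(k) fit_once(seed + k))
  best <- fits[[which.min(vapply(fits, function(f) f$loss, numeric(1)))]]
  structure(list(config = config, params = best$params,
                 train_loss = best$loss),
            class = "xchar_concept_classifier")
}

#' Predict classes from concept matrices with a fitted classifier head
#'
#' @param clf a [fit_concept_classifier()] result.
#' @param cms list of concept matrices.
#' @return character vector of class labels.
#' @export
predict_concept_classifier <- function(clf, cms) {
  cfg <- clf$config
  vapply(cms, function(cm) {
    rc <- conv1d_fwd(unclass(cm), clf$params$clf_W, clf$params$clf_b,
                     cfg$clf_kernel, 1L, "causal", with_cache = FALSE)
    logits <- drop(colMeans(rc$out) %*% clf$params$out_W) + clf$params$out_b
    cfg$classes[which.max(logits)]
  }, character(1))
}

#' Idealized one-hot concept matrix from ground-truth segments
#'
#' Converts a window's hidden segment boundaries (generator diagnostics)
#' into the T' x (M+1) matrix an oracle bottleneck would emit: each output
#' timestep is one-hot at the concept covering the center of its receptive
#' stride window, or at the blank for filler.
#'
#' @param window a [sensor_window()] with boundaries attached.
#' @param config the model's [xchar_config()].
#' @return a [concept_matrix()].
#' @export
ideal_concept_matrix <- function(window, config) {
  if (is.null(window$boundaries)) {
    stop("window has no ground-truth boundaries", call. = FALSE)
  }
  T_in <- ncol(window$values)
  t2 <- t_prime_len(T_in, config)
  stride <- config$conv1_stride * config$conv2_stride
  M1 <- length(config$concepts) + 1L
  P <- matrix(0, t2, M1)
  b <- window$boundaries
  for (t in seq_len(t2)) {
    center <- (t - 1) * stride + stride / 2
    hit <- which(b$start <= center & center < b$end)
    col <- if (length(hit) == 1) match(b$concept[hit], config$concepts) else M1
    P[t, col] <- 1
  }
  concept_matrix(P, config$concepts)
}
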