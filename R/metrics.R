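#' Macro (unweighted mean) F1-score
#'
#' Per-class F1 is the harmonic mean of precision and recall; the macro
#' score is their unweighted mean over classes. Classes absent from both the
#' truth and the predictions are excluded; a class with zero precision and
#' recall contributes an F1 of 0.
#'
#' @param truth,pred equal-length vectors of class labels.
#' @return scalar in `[0, 1]`.
#' @examples
#' macro_f1(c(1, 1, 2, 2), c(1, 2, 2, 2))  # 11/15
#' @export
macro_f1 <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) == 0 || length(truth) != length(pred)) {
    stop("truth and pred must be non-empty and of equal length", call. = FALSE)
  }
  classes <- sort(unique(c(truth, pred)))
  f1s <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp == 0 && (fp + fn) > 0) return(0)
    if (tp == 0) return(NA_real_)  # unreachable: class absent from both
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1s)
}

#' Evaluate a trained model on labeled windows
#'
#' Computes the row-normalized confusion matrix, per-class precision /
#' recall / F1, macro-F1, concept accuracy (the fraction of windows whose
#' beam-decoded concept sequence equals the labeled sequence exactly) and
#' the mean concept Levenshtein edit distance.
#'
#' @param model trained `xchar_model`.
#' @param windows labeled [sensor_window()] list.
#' @param beam_width decoding beam width.
#' @return object of class `xchar_eval`: a list with `confusion`
#'   (L x L, rows = truth, normalized to sum 1), `per_class`
#'   (data.frame), `macro_f1`, `concept_accuracy`, `mean_edit_distance`,
#'   `n`, and `decoded` (list of decoded sequences, for downstream use).
#' @export
evaluate_model <- function(model, windows,
                           beam_width = model$config$beam_width) {
  stopifnot(length(windows) >= 1)
  check_dataset_compat(model$config, windows)
  classes <- model$config$classes
  fwd <- model_forward(model, lapply(windows, function(w) w$values))
  pred <- classes[max.col(fwd$class_logP, ties.method = "first")]
  truth <- vapply(windows, function(w) w$class_label, character(1))

  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  for (i in seq_along(windows)) conf[truth[i], pred[i]] <- conf[truth[i], pred[i]] + 1
  rs <- rowSums(conf)
  norm_conf <- conf
  nonzero <- rs > 0
  norm_conf[nonzero, ] <- conf[nonzero, , drop = FALSE] / rs[nonzero]

  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(class = cl, precision = p, recall = r, f1 = f1,
               support = sum(truth == cl), stringsAsFactors = FALSE)
  }))

  decoded <- lapply(seq_along(windows), function(i) {
    rows <- (fwd$off[i] + 1):(fwd$off[i] + fwd$t2[i])
    cm <- concept_matrix(fwd$P[rows, , drop = FALSE], model$config$concepts)
    beam_decode(cm, beam_width)$sequence
  })
  exact <- vapply(seq_along(windows), function(i) {
    identical(decoded[[i]], windows[[i]]$concepts)
  }, logical(1))
  edits <- vapply(seq_along(windows), function(i) {
    levenshtein(decoded[[i]], windows[[i]]$concepts)
  }, numeric(1))

  structure(list(
    confusion = norm_conf,
    per_class = per_class,
    macro_f1 = macro_f1(truth, pred),
    concept_accuracy = mean(exact),
    mean_edit_distance = mean(edits),
    n = length(windows),
    predicted = pred,
    decoded = decoded
  ), class = "xchar_eval")
}

#' @export
print.xchar_eval <- function(x, ...) {
  cat("Evaluation on ", x$n, " windows\n", sep = "")
  cat(sprintf("  macro F1:           %.4f\n", x$macro_f1))
  cat(sprintf("  concept accuracy:   %.4f\n", x$concept_accuracy))
  cat(sprintf("  mean edit distance: %.4f\n", x$mean_edit_distance))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `xchar_eval`.
#' @param path JSON file path.
#' @return path, invisibly.
#' @export
write_eval <- function(report, path) {
  jsonlite::write_json(list(
    macro_f1 = report$macro_f1,
    concept_accuracy = report$concept_accuracy,
    mean_edit_distance = report$mean_edit_distance,
    n = report$n,
    confusion = as.data.frame(report$confusion),
    per_class = report$per_class
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Faithfulness perturbation protocol
#'
#' Three checks of whether the decoded-concept explanations track the
#' model's decisions:
#' \describe{
#'   \item{P1 (consistency)}{group test windows by decoded explanation; the
#'     fraction of groups whose members all share one predicted class.
#'     Faithful explanations imply identical predictions for identical
#'     explanations, i.e. P1 = 1.}
#'   \item{P2 (stability under noise)}{add channel-wise Gaussian noise with
#'     sd `noise_fraction` times each channel's sd; among windows whose
#'     prediction is unchanged, the fraction whose explanation is also
#'     unchanged.}
#'   \item{P3 (sensitivity to structure)}{cut each window into
#'     `n_shuffle_segments` time segments and permute them; the fractions of
#'     windows with changed prediction and changed explanation. Shuffling
#'     destroys the concept order, so both should usually change.}
#' }
#'
#' @param model trained `xchar_model`.
#' @param windows test windows.
#' @param noise_fraction Gaussian noise level relative to channel sd
#'   (default 0.05, i.e. 5\%).
#' @param n_shuffle_segments number of segments for the shuffle
#'   perturbation (>= 2).
#' @param seed RNG seed for noise and permutations.
#' @param beam_width decoding beam width.
#' @return list with `p1_consistency`, `p2_stability`,
#'   `p2_n` (windows with unchanged prediction under noise),
#'   `p3_pred_changed`, `p3_expl_changed`, and `n`.
#' @export
faithfulness_check <- function(model, windows, noise_fraction = 0.05,
                               n_shuffle_segments = 5L, seed = 1L,
                               beam_width = model$config$beam_width) {
  stopifnot(length(windows) >= 1, noise_fraction >= 0)
  if (n_shuffle_segments < 2) {
    stop("n_shuffle_segments must be >= 2", call. = FALSE)
  }
  base <- lapply(windows, function(w) {
    pred <- predict(model, w$values)
    list(class = pred$class_label,
         seq = beam_decode(pred$concept_matrix, beam_width)$sequence)
  })
  # P1: identical explanations -> identical predictions
  keys <- vapply(base, function(b) paste(b$seq, collapse = "\r"), character(1))
  cls <- vapply(base, function(b) b$class, character(1))
  groups <- split(cls, keys)
  p1 <- mean(vapply(groups, function(g) length(unique(g)) == 1, logical(1)))

  p2_same_expl <- logical(0)
  p3_pred_changed <- logical(length(windows))
  p3_expl_changed <- logical(length(windows))
  with_seed(seed, {
    for (i in seq_along(windows)) {
      v <- windows[[i]]$values
      # P2: channel-scaled Gaussian noise
      ch_sd <- apply(v, 1, stats::sd)
      noisy <- v + matrix(stats::rnorm(length(v)), nrow(v)) *
        (noise_fraction * ch_sd)
      pn <- predict(model, noisy)
      if (identical(pn$class_label, base[[i]]$class)) {
        sq <- beam_decode(pn$concept_matrix, beam_width)$sequence
        p2_same_expl <- c(p2_same_expl, identical(sq, base[[i]]$seq))
      }
      # P3: segment shuffle
      cuts <- floor(seq(0, ncol(v), length.out = n_shuffle_segments + 1))
      segs <- lapply(seq_len(n_shuffle_segments), function(k) {
        v[, (cuts[k] + 1):cuts[k + 1], drop = FALSE]
      })
      perm <- sample.int(n_shuffle_segments)
      if (identical(perm, seq_len(n_shuffle_segments))) {
        perm <- rev(perm)  # force a non-identity permutation
      }
      shuffled <- do.call(cbind, segs[perm])
      ps <- predict(model, shuffled)
      sq <- beam_decode(ps$concept_matrix, beam_width)$sequence
      p3_pred_changed[i] <- !identical(ps$class_label, base[[i]]$class)
      p3_expl_changed[i] <- !identical(sq, base[[i]]$seq)
    }
  })
  list(p1_consistency = p1,
       p2_stability = if (length(p2_same_expl)) mean(p2_same_expl) else NA_real_,
       p2_n = length(p2_same_expl),
       p3_pred_changed = mean(p3_pred_changed),
       p3_expl_changed = mean(p3_expl_changed),
       n = length(windows))
}
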