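#' Concept-sequence store for counterfactual search
#'
#' Harvests the decoded concept sequence and the model-predicted class of
#' every training window. The store reflects the model's own behavior (not
#' the ground-truth labels), so counterfactuals retrieved from it are
#' faithful to the model's decision boundary, and because every entry is a
#' training-derived sequence, counterfactuals are plausible by construction.
#' The store is built once and can be persisted as JSON.
#'
#' @param model trained `xchar_model`.
#' @param windows training windows (list of [sensor_window()]).
#' @param beam_width decoding beam width (default from the config).
#' @return object of class `concept_store`: a list with `entries` (each
#'   `list(sequence, class)`), `alphabet` and `classes`.
#' @export
build_store <- function(model, windows,
                        beam_width = model$config$beam_width) {
  if (length(windows) == 0) stop("empty training set", call. = FALSE)
  fwd <- model_forward(model, lapply(windows, function(w) w$values))
  pred_idx <- max.col(fwd$class_logP, ties.method = "first")
  entries <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    rows <- (fwd$off[i] + 1):(fwd$off[i] + fwd$t2[i])
    cm <- concept_matrix(fwd$P[rows, , drop = FALSE], model$config$concepts)
    entries[[i]] <- list(
      sequence = beam_decode(cm, beam_width)$sequence,
      class = model$config$classes[pred_idx[i]]
    )
  }
  structure(list(entries = entries,
                 alphabet = model$config$concepts,
                 classes = model$config$classes),
            class = "concept_store")
}

#' @export
print.concept_store <- function(x, ...) {
  cat("<concept_store> ", length(x$entries), " entries over ",
      length(x$alphabet), " concepts\n", sep = "")
  invisible(x)
}

#' Write / read a concept store as JSON
#'
#' @param store a `concept_store`.
#' @param path JSON file path.
#' @return `write_store`: the path, invisibly. `read_store`: the store.
#' @export
write_store <- function(store, path) {
  jsonlite::write_json(
    list(format = "xchar-concept-store",
         alphabet = as.list(store$alphabet),
         classes = as.list(store$classes),
         entries = lapply(store$entries, function(e)
           list(sequence = as.list(e$sequence), class = e$class))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  x <- jsonlite::read_json(path)
  structure(list(
    entries = lapply(x$entries, function(e)
      list(sequence = as.character(unlist(e$sequence)), class = e$class)),
    alphabet = unlist(x$alphabet),
    classes = unlist(x$classes)
  ), class = "concept_store")
}

#' Nearest different-class counterfactual sequence
#'
#' Among store entries whose predicted class differs from `predicted_class`,
#' returns the one with minimum Damerau-Levenshtein distance to `sequence`.
#' Distance-0 entries (an identical sequence mapped to another class) are
#' rejected so a counterfactual always differs from the query; ties are
#' broken by the entry's frequency in the store (most frequent first), then
#' lexicographically.
#'
#' @param store a `concept_store`.
#' @param sequence decoded concept sequence of the test window.
#' @param predicted_class the model's predicted class for the test window.
#' @return object of class `xchar_explanation` with fields `sequence`,
#'   `predicted_class`, `counterfactual`, `counterfactual_class`,
#'   `distance` and `available`. When no different-class entry exists,
#'   `available` is `FALSE` and the counterfactual fields are `NA`.
#' @export
counterfactual <- function(store, sequence, predicted_class) {
  stopifnot(inherits(store, "concept_store"))
  sequence <- as.character(sequence)
  other <- Filter(function(e) !identical(e$class, predicted_class),
                  store$entries)
  no_cf <- structure(
    list(sequence = sequence, predicted_class = predicted_class,
         counterfactual = NA, counterfactual_class = NA_character_,
         distance = NA_integer_, available = FALSE),
    class = "xchar_explanation")
  if (length(other) == 0) return(no_cf)
  d <- vapply(other, function(e) dl_distance(sequence, e$sequence),
              integer(1))
  ok <- d >= 1L  # identical sequence under a different class is rejected
  if (!any(ok)) return(no_cf)
  other <- other[ok]; d <- d[ok]
  dmin <- min(d)
  cand <- other[d == dmin]
  keys <- vapply(cand, function(e) paste(e$sequence, collapse = "\r"),
                 character(1))
  freq <- table(vapply(store$entries, function(e)
    paste(e$sequence, collapse = "\r"), character(1)))
  nfreq <- as.integer(freq[keys])
  nfreq[is.na(nfreq)] <- 0L
  best <- order(-nfreq, keys)[1]
  structure(
    list(sequence = sequence, predicted_class = predicted_class,
         counterfactual = cand[[best]]$sequence,
         counterfactual_class = cand[[best]]$class,
         distance = as.integer(dmin), available = TRUE),
    class = "xchar_explanation")
}

#' Explain a prediction
#'
#' Full explanation pipeline for one window: predict the class, beam-decode
#' the concept sequence from the bottleneck, retrieve the nearest
#' different-class counterfactual from the store, and report per-concept
#' alignment spans (argmax runs of the concept matrix mapped back to the
#' input timebase) for rendering.
#'
#' @param model trained `xchar_model`.
#' @param store a [build_store()] result.
#' @param values S x T matrix.
#' @param beam_width decoding beam width.
#' @return an `xchar_explanation` with the fields of [counterfactual()]
#'   plus `probability` (marginal probability of the decoded sequence) and
#'   `spans` (data.frame: `concept`, `start`, `end` in input samples,
#'   0-based half-open).
#' @export
explain <- function(model, store, values,
                    beam_width = model$config$beam_width) {
  pred <- predict(model, values)
  dec <- beam_decode(pred$concept_matrix, beam_width)
  ex <- counterfactual(store, dec$sequence, pred$class_label)
  ex$probability <- dec$probability
  ex$spans <- concept_spans(pred$concept_matrix, model$config)
  ex
}

# Argmax runs of the concept matrix, mapped to the input timebase by the
# total convolution stride; blank runs are dropped.
concept_spans <- function(cm, config) {
  stride <- config$conv1_stride * config$conv2_stride
  symbols <- colnames(cm)
  arg <- symbols[max.col(unclass(cm), ties.method = "first")]
  r <- rle(arg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != ctc_blank()
  data.frame(concept = r$values[keep],
             start = starts[keep] * stride,
             end = ends[keep] * stride)
}

#' @export
print.xchar_explanation <- function(x, ...) {
  cat("Prediction:     ", x$predicted_class, "\n", sep = "")
  cat("Concepts:       ", paste(x$sequence, collapse = " -> "), "\n", sep = "")
  if (isTRUE(x$available)) {
    cat("Counterfactual: ", paste(x$counterfactual, collapse = " -> "),
        "  [", x$counterfactual_class, ", distance ", x$distance, "]\n",
        sep = "")
  } else {
    cat("Counterfactual: none available\n")
  }
  invisible(x)
}

#' Serialize / restore an explanation as JSON
#'
#' @param x an `xchar_explanation`.
#' @param path JSON file path.
#' @return `write_explanation`: path invisibly; `read_explanation`: the
#'   explanation.
#' @export
write_explanation <- function(x, path) {
  out <- list(
    sequence = as.list(x$sequence),
    predicted_class = x$predicted_class,
    counterfactual = if (isTRUE(x$available)) as.list(x$counterfactual),
    counterfactual_class = if (isTRUE(x$available)) x$counterfactual_class,
    distance = if (isTRUE(x$available)) x$distance,
    available = isTRUE(x$available),
    probability = x$probability,
    spans = x$spans
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_explanation
#' @export
read_explanation <- function(path) {
  j <- jsonlite::read_json(path)
  structure(list(
    sequence = as.character(unlist(j$sequence)),
    predicted_class = j$predicted_class,
    counterfactual = if (isTRUE(j$available)) as.character(unlist(j$counterfactual)) else NA,
    counterfactual_class = if (isTRUE(j$available)) j$counterfactual_class else NA_character_,
    distance = if (isTRUE(j$available)) as.integer(j$distance) else NA_integer_,
    available = isTRUE(j$available),
    probability = if (!is.null(j$probability)) as.numeric(j$probability),
    spans = if (!is.null(j$spans)) as.data.frame(lapply(j$spans, unlist),
                                                 stringsAsFactors = FALSE)
  ), class = "xchar_explanation")
}
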