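#' Concept grammars for complex activities
#'
#' A concept grammar maps each complex-activity class to the set of concept
#' sequences that realize it. A complex activity is a pattern of two or more
#' concept instances whose order matters, so every sequence must have length
#' at least 2, and a given sequence may belong to at most one class
#' (otherwise the classes would be indistinguishable from the concept
#' sequence alone).
#'
#' @param concepts character vector of unique concept identifiers.
#' @param sequences named list: one entry per class, each a list of character
#'   vectors (the admissible concept sequences for that class).
#' @return An object of class `concept_grammar` with elements `concepts`,
#'   `classes` and `sequences`.
#' @examples
#' g <- concept_grammar(
#'   concepts = c("A", "B", "C"),
#'   sequences = list(cls1 = list(c("A", "B")), cls2 = list(c("B", "A", "C")))
#' )
#' g$classes
#' @export
concept_grammar <- function(concepts, sequences) {
  concepts <- as.character(concepts)
  if (anyDuplicated(concepts) > 0) {
    stop("concept identifiers must be unique", call. = FALSE)
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("`sequences` must be a named list (one entry per class)", call. = FALSE)
  }
  classes <- names(sequences)
  if (anyDuplicated(classes) > 0) {
    stop("class identifiers must be unique", call. = FALSE)
  }
  sequences <- lapply(sequences, function(seqs) {
    if (length(seqs) == 0) stop("every class needs at least one sequence", call. = FALSE)
    lapply(seqs, as.character)
  })
  for (cls in classes) {
    for (s in sequences[[cls]]) {
      if (length(s) < 2) {
        stop("complex activities are sequences of >= 2 concepts; class '",
             cls, "' has a shorter one", call. = FALSE)
      }
      unknown <- setdiff(s, concepts)
      if (length(unknown) > 0) {
        stop("sequence for class '", cls, "' references unknown concept(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
    }
  }
  # the class -> sequence map must be a function: no sequence under two classes
  keys <- unlist(lapply(classes, function(cls) {
    vapply(sequences[[cls]], paste, character(1), collapse = "\r")
  }))
  owner <- rep(classes, vapply(sequences, length, integer(1)))
  by_key <- split(owner, keys)
  shared <- names(by_key)[vapply(by_key, function(o) length(unique(o)) > 1, logical(1))]
  if (length(shared) > 0) {
    stop("the same concept sequence appears under two classes: ",
         gsub("\r", " -> ", shared[1]), call. = FALSE)
  }
  structure(
    list(concepts = concepts, classes = classes, sequences = sequences),
    class = "concept_grammar"
  )
}

#' @export
print.concept_grammar <- function(x, ...) {
  cat("Concept grammar: ", length(x$classes), " classes, ",
      length(x$concepts), " concepts\n", sep = "")
  for (cls in x$classes) {
    cat("  ", cls, ":\n", sep = "")
    for (s in x$sequences[[cls]]) {
      cat("    ", paste(s, collapse = " -> "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Nurse-activity concept grammar
#'
#' The five complex nursing activities (physiological measurement, patient
#' cleaning, unsanitary operations, safe and unsafe IV/drips procedures) and
#' their sixteen admissible concept sequences over six nursing concepts
#' (checking vitals, blood collection, blood glucose measurement, oral care,
#' patient cleaning, drips). This grammar is the canonical fixture for the
#' synthetic benchmark: classes differ only in the order of largely shared
#' concepts, so recognizing them requires sequence information, not just
#' concept presence.
#'
#' @return A [concept_grammar()] with 5 classes, 6 concepts and 16 sequences.
#' @examples
#' g <- make_nurse_grammar()
#' length(g$concepts)
#' @export
make_nurse_grammar <- function() {
  concept_grammar(
    concepts = c("Vitals", "Blood collection", "Blood glucose",
                 "Oral care", "Clean", "Drips"),
    sequences = list(
      "Physiological Measurement" = list(
        c("Vitals", "Blood collection", "Blood glucose"),
        c("Blood collection", "Vitals", "Blood glucose")
      ),
      "Patient Cleaning" = list(
        c("Vitals", "Oral care", "Clean"),
        c("Oral care", "Vitals", "Clean"),
        c("Oral care", "Blood glucose", "Clean"),
        c("Blood glucose", "Oral care", "Clean")
      ),
      "Unsanitary Operations" = list(
        c("Clean", "Blood glucose", "Vitals"),
        c("Clean", "Oral care", "Vitals"),
        c("Vitals", "Clean", "Oral care"),
        c("Oral care", "Clean", "Blood glucose")
      ),
      "Safe IV/Drips Procedure" = list(
        c("Vitals", "Blood collection", "Drips", "Vitals"),
        c("Vitals", "Drips", "Vitals"),
        c("Vitals", "Drips", "Blood collection", "Vitals")
      ),
      "Unsafe IV/Drips Procedure" = list(
        c("Vitals", "Blood collection", "Drips"),
        c("Blood collection", "Drips", "Vitals"),
        c("Drips", "Blood collection", "Vitals")
      )
    )
  )
}

#' Does a concept sequence belong to a class under a grammar?
#'
#' @param grammar a [concept_grammar()].
#' @param sequence character vector of concepts.
#' @param class optional class; if omitted, any class counts.
#' @return logical scalar.
#' @export
grammar_contains <- function(grammar, sequence, class = NULL) {
  stopifnot(inherits(grammar, "concept_grammar"))
  classes <- if (is.null(class)) grammar$classes else class
  key <- paste(as.character(sequence), collapse = "\r")
  for (cls in classes) {
    keys <- vapply(grammar$sequences[[cls]], paste, character(1), collapse = "\r")
    if (key %in% keys) return(TRUE)
  }
  FALSE
}
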