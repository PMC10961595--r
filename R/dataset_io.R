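#' Write a dataset to disk
#'
#' Serializes a list of [sensor_window()] objects as one CSV file per window
#' (channels as columns) plus a JSON manifest recording class labels, concept
#' sequences, the grammar and generation provenance. The manifest carries the
#' weak-supervision view only: hidden segment boundaries are deliberately not
#' written.
#'
#' @param windows list of [sensor_window()].
#' @param directory output directory (created if needed).
#' @param grammar optional [concept_grammar()] to embed for validation on read.
#' @param params optional list of generator parameters (stored verbatim).
#' @param seed optional seed to record.
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(windows, directory, grammar = NULL, params = NULL,
                          seed = NULL) {
  if (length(windows) == 0) stop("empty dataset", call. = FALSE)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    file <- sprintf("window_%05d.csv", i)
    df <- as.data.frame(t(w$values))
    names(df) <- sprintf("ch%d", seq_len(nrow(w$values)))
    utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     file.path(directory, file), row.names = FALSE,
                     quote = FALSE)
    entries[[i]] <- list(file = file, class = w$class_label,
                         concepts = as.list(w$concepts),
                         n_channels = nrow(w$values),
                         n_samples = ncol(w$values))
  }
  manifest <- list(
    format = "xchar-dataset",
    version = 1L,
    n_windows = length(windows),
    grammar = if (!is.null(grammar)) grammar_to_list(grammar),
    params = params,
    seed = seed,
    windows = entries
  )
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param directory dataset directory containing `manifest.json`.
#' @return list of [sensor_window()] with attributes `grammar`, `params` and
#'   `seed` (when recorded in the manifest).
#' @export
read_dataset <- function(directory) {
  path <- file.path(directory, "manifest.json")
  if (!file.exists(path)) {
    stop("no dataset found: missing manifest at ", path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(path)
  if (is.null(manifest$windows) || length(manifest$windows) == 0) {
    stop("empty dataset: manifest lists no windows", call. = FALSE)
  }
  grammar <- if (!is.null(manifest$grammar)) grammar_from_list(manifest$grammar)
  windows <- vector("list", length(manifest$windows))
  for (i in seq_along(manifest$windows)) {
    e <- manifest$windows[[i]]
    f <- file.path(directory, e$file)
    if (!file.exists(f)) {
      stop("manifest references missing array file: ", e$file, call. = FALSE)
    }
    concepts <- unlist(e$concepts)
    if (!is.null(grammar)) {
      unknown <- setdiff(concepts, grammar$concepts)
      if (length(unknown) > 0) {
        stop("window ", i, " labeled with concept(s) not in grammar: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
    }
    df <- utils::read.csv(f)
    values <- t(as.matrix(df))
    dimnames(values) <- NULL
    if (nrow(values) != e$n_channels || ncol(values) != e$n_samples) {
      stop("array file ", e$file, " does not match manifest shape", call. = FALSE)
    }
    windows[[i]] <- sensor_window(values, e$class, concepts)
  }
  attr(windows, "grammar") <- grammar
  attr(windows, "params") <- manifest$params
  attr(windows, "seed") <- manifest$seed
  windows
}

grammar_to_list <- function(grammar) {
  list(
    concepts = as.list(grammar$concepts),
    classes = as.list(grammar$classes),
    sequences = lapply(grammar$sequences, function(seqs) lapply(seqs, as.list))
  )
}

grammar_from_list <- function(x) {
  concept_grammar(
    concepts = unlist(x$concepts),
    sequences = lapply(x$sequences, function(seqs) lapply(seqs, unlist))
  )
}
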