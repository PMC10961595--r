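#' Save / load a model checkpoint
#'
#' The checkpoint is a directory with `config.json` (architecture and
#' training configuration), `weights.json` (every parameter array with its
#' dimensions, full double precision) and `norm.json` (the fitted
#' per-channel normalization). Plain-text containers keep checkpoints
#' portable and diffable.
#'
#' @param model an `xchar_model`.
#' @param directory checkpoint directory (created if needed).
#' @return `save_model`: directory, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  cfg <- model$config
  jsonlite::write_json(unclass(cfg), file.path(directory, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  weights <- lapply(model$params, function(p) {
    list(dim = if (is.matrix(p)) dim(p) else length(p), values = as.numeric(p))
  })
  jsonlite::write_json(weights, file.path(directory, "weights.json"),
                       digits = I(17))
  if (!is.null(model$norm)) {
    jsonlite::write_json(model$norm, file.path(directory, "norm.json"),
                         digits = I(17))
  }
  if (!is.null(model$history)) {
    utils::write.csv(model$history, file.path(directory, "history.csv"),
                     row.names = FALSE)
  }
  invisible(directory)
}

#' @rdname save_model
#' @export
load_model <- function(directory) {
  cfg_path <- file.path(directory, "config.json")
  if (!file.exists(cfg_path)) {
    stop("not a checkpoint directory: missing ", cfg_path, call. = FALSE)
  }
  raw <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  cfg <- xchar_config(
    concepts = raw$concepts, classes = raw$classes,
    n_channels = raw$n_channels,
    conv1_filters = raw$conv1_filters, conv1_kernel = raw$conv1_kernel,
    conv1_stride = raw$conv1_stride,
    conv2_filters = raw$conv2_filters, conv2_kernel = raw$conv2_kernel,
    conv2_stride = raw$conv2_stride,
    lstm_units = raw$lstm_units,
    clf_filters = raw$clf_filters, clf_kernel = raw$clf_kernel,
    beta = raw$beta, lr = raw$lr, batch_size = raw$batch_size,
    epochs = raw$epochs, patience = raw$patience,
    beam_width = raw$beam_width, seed = raw$seed)
  w <- jsonlite::read_json(file.path(directory, "weights.json"),
                           simplifyVector = TRUE)
  params <- lapply(w, function(e) {
    v <- as.numeric(e$values)
    if (length(e$dim) == 2) matrix(v, e$dim[1], e$dim[2]) else v
  })
  norm <- NULL
  if (file.exists(file.path(directory, "norm.json"))) {
    n <- jsonlite::read_json(file.path(directory, "norm.json"),
                             simplifyVector = TRUE)
    norm <- list(mean = as.numeric(n$mean), sd = as.numeric(n$sd))
  }
  history <- NULL
  if (file.exists(file.path(directory, "history.csv"))) {
    history <- utils::read.csv(file.path(directory, "history.csv"))
  }
  structure(list(config = cfg, params = params, norm = norm,
                 history = history),
            class = "xchar_model")
}
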