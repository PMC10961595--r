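#' Concept signal prototypes
#'
#' A prototype describes how a concept manifests in the sensor channels: a
#' band-limited oscillation with concept-specific frequency, per-channel
#' amplitude and DC offset, plus a duration range (in samples) from which
#' each realization's length is drawn. Distinct concepts must differ in at
#' least one parameter so that they are recoverable in principle.
#'
#' @param concept concept identifier.
#' @param freq oscillation frequency in cycles per sample (scalar or one per
#'   channel).
#' @param amplitude per-channel amplitude (recycled to `n_channels`).
#' @param offset per-channel DC offset (recycled).
#' @param dur_range integer vector `c(min, max)` duration in samples, min >= 1.
#' @param n_channels number of sensor channels S.
#' @return object of class `concept_prototype`.
#' @export
concept_prototype <- function(concept, freq, amplitude = 1, offset = 0,
                              dur_range = c(30L, 60L), n_channels = 3L) {
  dur_range <- as.integer(round(dur_range))
  if (length(dur_range) != 2 || dur_range[1] < 1 || dur_range[2] < dur_range[1]) {
    stop("dur_range must be c(min, max) with min >= 1", call. = FALSE)
  }
  structure(
    list(
      concept = as.character(concept),
      freq = rep_len(freq, n_channels),
      amplitude = rep_len(amplitude, n_channels),
      offset = rep_len(offset, n_channels),
      dur_range = dur_range,
      n_channels = as.integer(n_channels)
    ),
    class = "concept_prototype"
  )
}

#' Default prototype bank for a grammar
#'
#' Assigns each concept a distinct oscillation frequency (spread across a
#' low-frequency band, as accelerometer motion motifs would be), staggered
#' per-channel amplitudes and a concept-specific DC offset pattern. The
#' defaults render the 30-60 second segments of the nursing benchmark at a
#' 1 Hz-equivalent rate (30-60 samples per concept).
#'
#' @param grammar a [concept_grammar()].
#' @param n_channels number of sensor channels (default 3, tri-axial).
#' @param dur_range duration range in samples for every concept.
#' @return named list of [concept_prototype()] objects, one per concept.
#' @export
default_prototypes <- function(grammar, n_channels = 3L,
                               dur_range = c(30L, 60L)) {
  stopifnot(inherits(grammar, "concept_grammar"))
  m <- length(grammar$concepts)
  protos <- vector("list", m)
  names(protos) <- grammar$concepts
  for (i in seq_len(m)) {
    base_freq <- 0.05 + 0.04 * (i - 1)          # cycles/sample, well below Nyquist
    ch <- seq_len(n_channels) - 1
    protos[[i]] <- concept_prototype(
      concept = grammar$concepts[i],
      freq = base_freq * (1 + 0.15 * ch),
      amplitude = 1.0 - 0.2 * ch,
      # per-concept offset pattern alternating across channels
      offset = 0.5 * cos(pi * ch / 2 + 2 * pi * (i - 1) / m),
      dur_range = dur_range,
      n_channels = n_channels
    )
  }
  protos
}

render_segment <- function(proto, duration) {
  t <- seq_len(duration) - 1
  phase <- stats::runif(proto$n_channels, 0, 2 * pi)
  vals <- vapply(seq_len(proto$n_channels), function(ch) {
    proto$offset[ch] +
      proto$amplitude[ch] * sin(2 * pi * proto$freq[ch] * t + phase[ch])
  }, numeric(duration))
  t(vals)  # S x duration
}

#' A labeled multivariate sensor window
#'
#' Bundles an S x T signal with its complex-activity class label and the
#' ordered (weak, timestamp-free) concept-sequence label. Hidden ground-truth
#' segment boundaries may be attached for diagnostics only; they are never
#' serialized with the training-facing view.
#'
#' @param values numeric matrix, channels x samples (S x T), no missing values.
#' @param class_label complex-activity class.
#' @param concepts character vector, ordered concept sequence (length >= 2).
#' @param boundaries optional data.frame with columns `concept`, `start`,
#'   `end` (0-based half-open sample intervals, sorted, non-overlapping).
#' @return object of class `sensor_window`.
#' @export
sensor_window <- function(values, class_label, concepts, boundaries = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("sensor values must not contain NA", call. = FALSE)
  concepts <- as.character(concepts)
  if (length(concepts) < 2) {
    stop("a complex activity has >= 2 concepts", call. = FALSE)
  }
  if (!is.null(boundaries)) {
    stopifnot(all(c("concept", "start", "end") %in% names(boundaries)))
    if (is.unsorted(boundaries$start) ||
        any(boundaries$end <= boundaries$start) ||
        any(boundaries$start < 0) || any(boundaries$end > ncol(values)) ||
        any(utils::head(boundaries$end, -1) > utils::tail(boundaries$start, -1))) {
      stop("boundaries must be sorted, non-overlapping, within [0, T)", call. = FALSE)
    }
  }
  structure(
    list(values = values, class_label = as.character(class_label),
         concepts = concepts, boundaries = boundaries),
    class = "sensor_window"
  )
}

#' @export
print.sensor_window <- function(x, ...) {
  cat("<sensor_window> ", nrow(x$values), " x ", ncol(x$values),
      "  class: ", x$class_label,
      "  concepts: ", paste(x$concepts, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic complex-activity dataset
#'
#' Emulates the construction of the complex nursing benchmark: for each
#' class, a concept sequence is drawn uniformly from the class grammar, each
#' concept is rendered as a prototype realization of random duration, and
#' segments are concatenated in order, optionally interleaved with short
#' unlabeled filler motion (low-amplitude, zero-mean noise with no semantic
#' meaning). Only the sequence-level concept labels are exposed; the true
#' segment boundaries are retained as a hidden diagnostic attribute.
#'
#' @param grammar a [concept_grammar()].
#' @param prototypes named list of [concept_prototype()] covering every
#'   grammar concept (default [default_prototypes()]).
#' @param n_per_class windows to draw per class (>= 1).
#' @param noise_sd standard deviation of i.i.d. Gaussian channel noise added
#'   to every sample (>= 0).
#' @param filler_prob probability of inserting a filler segment between two
#'   consecutive concepts.
#' @param filler_range duration range (samples) of filler segments.
#' @param filler_sd amplitude (sd) of filler motion.
#' @param seed integer seed; the dataset is a deterministic function of all
#'   arguments.
#' @return list of [sensor_window()] objects
#'   (length `n_per_class * length(grammar$classes)`).
#' @examples
#' g <- make_nurse_grammar()
#' d <- generate_dataset(g, n_per_class = 2, seed = 1)
#' length(d)
#' @export
generate_dataset <- function(grammar, prototypes = default_prototypes(grammar),
                             n_per_class = 1L, noise_sd = 0.1,
                             filler_prob = 0.5, filler_range = c(0L, 10L),
                             filler_sd = 0.1, seed = 1L) {
  stopifnot(inherits(grammar, "concept_grammar"))
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  missing_protos <- setdiff(grammar$concepts, names(prototypes))
  if (length(missing_protos) > 0) {
    stop("no prototype for concept(s): ",
         paste(missing_protos, collapse = ", "), call. = FALSE)
  }
  n_channels <- prototypes[[1]]$n_channels
  windows <- vector("list", n_per_class * length(grammar$classes))
  i <- 0L
  with_seed(seed, {
    for (cls in grammar$classes) {
      seqs <- grammar$sequences[[cls]]
      for (r in seq_len(n_per_class)) {
        cseq <- seqs[[sample.int(length(seqs), 1)]]
        segs <- list()
        bounds <- data.frame(concept = character(0), start = integer(0),
                             end = integer(0), stringsAsFactors = FALSE)
        pos <- 0L
        for (j in seq_along(cseq)) {
          proto <- prototypes[[cseq[j]]]
          dur <- sample_int_range(proto$dur_range)
          seg <- render_segment(proto, dur)
          segs[[length(segs) + 1L]] <- seg
          bounds <- rbind(bounds, data.frame(
            concept = cseq[j], start = pos, end = pos + dur,
            stringsAsFactors = FALSE))
          pos <- pos + dur
          if (j < length(cseq) && stats::runif(1) < filler_prob) {
            fdur <- sample_int_range(filler_range)
            if (fdur > 0) {
              segs[[length(segs) + 1L]] <-
                matrix(stats::rnorm(n_channels * fdur, 0, filler_sd),
                       nrow = n_channels)
              pos <- pos + fdur
            }
          }
        }
        values <- do.call(cbind, segs)
        if (noise_sd > 0) {
          values <- values + matrix(stats::rnorm(length(values), 0, noise_sd),
                                    nrow = nrow(values))
        }
        i <- i + 1L
        windows[[i]] <- sensor_window(values, cls, cseq, boundaries = bounds)
      }
    }
  })
  windows
}

sample_int_range <- function(range) {
  if (range[1] == range[2]) return(as.integer(range[1]))
  as.integer(range[1]) + sample.int(range[2] - range[1] + 1L, 1L) - 1L
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
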