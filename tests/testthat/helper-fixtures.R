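# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept tiny so unit tests stay fast.

tiny_grammar <- function() {
  concept_grammar(
    concepts = c("A", "B", "C"),
    sequences = list(
      one = list(c("A", "B"), c("A", "C", "B")),
      two = list(c("B", "A"), c("C", "A"))
    )
  )
}

tiny_prototypes <- function(grammar = tiny_grammar(), n_channels = 2L) {
  default_prototypes(grammar, n_channels = n_channels,
                     dur_range = c(8L, 14L))
}

tiny_windows <- function(n_per_class = 2L, seed = 1L, ...) {
  g <- tiny_grammar()
  generate_dataset(g, tiny_prototypes(g), n_per_class = n_per_class,
                   filler_range = c(0L, 3L), seed = seed, ...)
}

tiny_config <- function(epochs = 2L, ...) {
  g <- tiny_grammar()
  xchar_config(
    concepts = g$concepts, classes = g$classes, n_channels = 2L,
    conv1_filters = 4L, conv1_kernel = 5L,
    conv2_filters = 6L, conv2_kernel = 5L,
    lstm_units = 5L, clf_filters = 4L, clf_kernel = 3L,
    batch_size = 4L, epochs = epochs, ...
  )
}

random_concept_matrix <- function(t_prime, m, concepts = LETTERS[seq_len(m)]) {
  p <- matrix(stats::rexp(t_prime * (m + 1)), t_prime)
  concept_matrix(p / rowSums(p), concepts)
}

random_sequence <- function(alphabet, max_len = 4L, min_len = 0L) {
  k <- sample(min_len:max_len, 1)
  if (k == 0) character(0) else sample(alphabet, k, replace = TRUE)
}
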