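mk_store <- function(entries) {
  structure(list(
    entries = entries,
    alphabet = LETTERS[1:4],
    classes = unique(vapply(entries, function(e) e$class, character(1)))
  ), class = "concept_store")
}

test_that("the nearest different-class sequence is returned", {
  store <- mk_store(list(
    list(sequence = c("A", "B", "C"), class = "class1"),
    list(sequence = c("A", "C", "B"), class = "class2"),
    list(sequence = c("D", "D"), class = "class2")
  ))
  ex <- counterfactual(store, c("A", "B", "C"), "class1")
  expect_true(ex$available)
  expect_equal(ex$counterfactual, c("A", "C", "B"))
  expect_equal(ex$counterfactual_class, "class2")
  expect_equal(ex$distance, 1L)
})

test_that("distance-0 cross-class collisions are rejected", {
  store <- mk_store(list(
    list(sequence = c("A", "B"), class = "class1"),
    list(sequence = c("A", "B"), class = "class2"),   # identical, other class
    list(sequence = c("A", "B", "C"), class = "class2")
  ))
  ex <- counterfactual(store, c("A", "B"), "class1")
  expect_true(ex$available)
  expect_gte(ex$distance, 1L)
  expect_equal(ex$counterfactual, c("A", "B", "C"))
})

test_that("a store without different-class entries yields no counterfactual", {
  store <- mk_store(list(list(sequence = c("A", "B"), class = "class1")))
  ex <- counterfactual(store, c("A", "B"), "class1")
  expect_false(ex$available)
  expect_true(is.na(ex$counterfactual_class))
})

test_that("returned counterfactuals are brute-force optimal", {
  set.seed(17)
  classes <- c("u", "v", "w")
  for (rep in 1:20) {
    entries <- lapply(1:15, function(i) {
      list(sequence = random_sequence(LETTERS[1:4], 4, 1),
           class = sample(classes, 1))
    })
    store <- mk_store(entries)
    q <- random_sequence(LETTERS[1:4], 4, 1)
    cls <- sample(classes, 1)
    ex <- counterfactual(store, q, cls)
    eligible <- Filter(function(e) e$class != cls &&
                         dl_distance(q, e$sequence) >= 1, entries)
    if (length(eligible) == 0) {
      expect_false(ex$available)
    } else {
      dmin <- min(vapply(eligible, function(e) dl_distance(q, e$sequence),
                         integer(1)))
      expect_equal(ex$distance, dmin)
      expect_true(ex$counterfactual_class != cls)
      # the returned sequence really is in the store at that distance
      expect_true(any(vapply(eligible, function(e) {
        identical(e$sequence, ex$counterfactual) &&
          dl_distance(q, e$sequence) == dmin
      }, logical(1))))
    }
  }
})

test_that("equidistant ties resolve to the most frequent store sequence", {
  store <- mk_store(list(
    list(sequence = c("A", "B"), class = "c1"),
    list(sequence = c("B", "C"), class = "c2"),
    list(sequence = c("B", "C"), class = "c2"),
    list(sequence = c("A", "C"), class = "c2")
  ))
  # both [B,C] and [A,C] are at distance 1 from [B,C]? use query [C,C]:
  # dl([C,C],[B,C]) = 1, dl([C,C],[A,C]) = 1 -> frequency picks [B,C]
  ex <- counterfactual(store, c("C", "C"), "c1")
  expect_equal(ex$counterfactual, c("B", "C"))
})

test_that("the store round-trips through JSON", {
  store <- mk_store(list(
    list(sequence = c("A", "B", "C"), class = "x"),
    list(sequence = c("C"), class = "y")
  ))
  path <- withr::local_tempfile(fileext = ".json")
  write_store(store, path)
  s2 <- read_store(path)
  expect_equal(s2$entries, store$entries)
  expect_equal(s2$alphabet, store$alphabet)
})

test_that("explanations round-trip through JSON", {
  ex <- structure(list(
    sequence = c("A", "B"), predicted_class = "x",
    counterfactual = c("B", "A"), counterfactual_class = "y",
    distance = 1L, available = TRUE, probability = 0.73,
    spans = data.frame(concept = c("A", "B"), start = c(0, 16),
                       end = c(12, 40))
  ), class = "xchar_explanation")
  path <- withr::local_tempfile(fileext = ".json")
  write_explanation(ex, path)
  ex2 <- read_explanation(path)
  expect_equal(ex2$sequence, ex$sequence)
  expect_equal(ex2$counterfactual, ex$counterfactual)
  expect_equal(ex2$distance, ex$distance)
  expect_equal(ex2$probability, ex$probability)
  expect_equal(ex2$spans, ex$spans)
})

test_that("argmax spans map back to the input timebase", {
  cfg <- tiny_config()
  # build a concept matrix with known argmax runs: A for 3 steps, blank 2, B 4
  p <- matrix(0.01, 9, 4)
  p[1:3, 1] <- 0.9; p[4:5, 4] <- 0.9; p[6:9, 2] <- 0.9
  cm <- concept_matrix(p / rowSums(p), cfg$concepts)
  spans <- xchar:::concept_spans(cm, cfg)
  expect_equal(spans$concept, c("A", "B"))
  expect_equal(spans$start, c(0, 5) * 4)
  expect_equal(spans$end, c(3, 9) * 4)
})

test_that("explaining the same window twice is deterministic", {
  d <- tiny_windows(n_per_class = 3, seed = 8)
  m <- train_model(build_model(tiny_config(seed = 4)), d, epochs = 1)
  store <- build_store(m, d)
  expect_equal(length(store$entries), length(d))
  e1 <- explain(m, store, d[[1]]$values)
  e2 <- explain(m, store, d[[1]]$values)
  expect_identical(e1, e2)
})
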