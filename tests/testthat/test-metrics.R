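test_that("macro F1 matches hand-computed cases", {
  expect_equal(macro_f1(c(1, 2), c(1, 2)), 1)
  expect_equal(macro_f1(c(1, 1, 2, 2), c(1, 2, 2, 2)), 11 / 15)
  expect_equal(macro_f1(c(1, 1, 2, 2), c(2, 2, 1, 1)), 0)
  expect_error(macro_f1(character(0), character(0)), "non-empty")
})

test_that("macro F1 agrees with a confusion-matrix recomputation", {
  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    n <- sample(5:40, 1)
    truth <- sample(letters[1:k], n, replace = TRUE)
    pred <- sample(letters[1:k], n, replace = TRUE)
    lev <- sort(unique(c(truth, pred)))
    tab <- table(factor(truth, lev), factor(pred, lev))
    f1s <- vapply(seq_along(lev), function(j) {
      tp <- tab[j, j]
      prec <- if (sum(tab[, j]) > 0) tp / sum(tab[, j]) else 0
      rec <- if (sum(tab[j, ]) > 0) tp / sum(tab[j, ]) else 0
      if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    }, numeric(1))
    expect_equal(macro_f1(truth, pred), mean(f1s), tolerance = 1e-12)
  }
})

test_that("evaluation reports are internally consistent", {
  d <- tiny_windows(n_per_class = 3, seed = 12)
  m <- train_model(build_model(tiny_config(seed = 7)), d, epochs = 1)
  ev <- evaluate_model(m, d)
  expect_equal(unname(rowSums(ev$confusion)), rep(1, ncol(ev$confusion)),
               tolerance = 1e-9)
  expect_gte(ev$macro_f1, 0); expect_lte(ev$macro_f1, 1)
  expect_gte(ev$mean_edit_distance, 0)
  expect_gte(ev$concept_accuracy, 0); expect_lte(ev$concept_accuracy, 1)
  expect_equal(ev$n, length(d))
  # exact-match accuracy and edit distance cohere: exact matches have
  # distance zero
  zero_edit <- vapply(seq_along(d), function(i) {
    levenshtein(ev$decoded[[i]], d[[i]]$concepts) == 0
  }, logical(1))
  expect_equal(mean(zero_edit), ev$concept_accuracy)
  # report serializes
  path <- withr::local_tempfile(fileext = ".json")
  write_eval(ev, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$macro_f1, ev$macro_f1)
  expect_equal(j$n, ev$n)
})

test_that("single-class evaluation gives a one-hot confusion row", {
  d <- tiny_windows(n_per_class = 3, seed = 13)
  m <- train_model(build_model(tiny_config(seed = 7)), d, epochs = 1)
  one <- Filter(function(w) w$class_label == "one", d)
  ev <- evaluate_model(m, one)
  expect_equal(sum(ev$confusion["one", ]), 1, tolerance = 1e-9)
  expect_equal(sum(ev$confusion["two", ]), 0)
})

test_that("zero noise leaves predictions and explanations unchanged", {
  d <- tiny_windows(n_per_class = 2, seed = 14)
  m <- train_model(build_model(tiny_config(seed = 3)), d, epochs = 1)
  rep <- faithfulness_check(m, d, noise_fraction = 0, seed = 5)
  expect_equal(rep$p2_stability, 1.0)
  expect_equal(rep$p2_n, length(d))
  expect_gte(rep$p1_consistency, 0); expect_lte(rep$p1_consistency, 1)
  expect_error(faithfulness_check(m, d, n_shuffle_segments = 1),
               "n_shuffle_segments")
})
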