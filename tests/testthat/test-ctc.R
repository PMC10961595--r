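eps <- ctc_blank()

test_that("collapse merges repeats then removes blanks", {
  expect_equal(collapse_path(c(eps, "A", "A", eps, "B")), c("A", "B"))
  expect_equal(collapse_path(c("A", eps, "A")), c("A", "A"))
  expect_equal(collapse_path(c(eps, eps, eps)), character(0))
  expect_equal(collapse_path(character(0)), character(0))
  expect_error(collapse_path(c("A", "Z"), concepts = "A"), "unknown symbol")
  # idempotence: collapsing an already-collapsed (blank-free, run-length-1)
  # sequence changes nothing
  for (i in 1:20) {
    p <- sample(c("A", "B", "C", eps), 6, replace = TRUE)
    cp <- collapse_path(p)
    if (length(cp) == 0 || !any(cp[-1] == utils::head(cp, -1))) {
      expect_equal(collapse_path(cp), cp)
    }
  }
})

test_that("alignment enumeration matches hand counts", {
  al <- enumerate_alignments(c("A", "B"), 3, c("A", "B"))
  expect_length(al, 5)
  keys <- sort(vapply(al, paste, character(1), collapse = ""))
  expect_equal(keys, sort(c("AAB", "ABB", paste0("AB", eps),
                            paste0("A", eps, "B"), paste0(eps, "AB"))))
  expect_length(enumerate_alignments(c("A", "A"), 2, "A"), 0)
  expect_equal(enumerate_alignments("A", 1, "A"), list("A"))
})

test_that("ctc_loss agrees with exhaustive alignment enumeration", {
  p <- concept_matrix(matrix(1 / 3, 3, 3), c("A", "B"))
  expect_equal(ctc_loss(p, c("A", "B")), -log(5 / 27), tolerance = 1e-12)
  # certain path
  p1 <- concept_matrix(matrix(c(1, 0), 1), "A")
  expect_equal(ctc_loss(p1, "A"), 0)
  # infeasible targets: too few timesteps, or a repeat with no room for the
  # separating blank
  p2 <- concept_matrix(matrix(1 / 3, 1, 3), c("A", "B"))
  expect_equal(ctc_loss(p2, c("A", "B")), Inf)
  expect_equal(ctc_loss(concept_matrix(matrix(0.5, 1, 2), "A"), c("A", "A")),
               Inf)
  # randomized oracle equivalence
  set.seed(1)
  for (i in 1:40) {
    m <- sample(1:3, 1)
    t_ <- sample(2:5, 1)
    cm <- random_concept_matrix(t_, m)
    target <- random_sequence(LETTERS[1:m], max_len = 3, min_len = 1)
    oracle <- oracle_ctc_prob(cm, target)
    loss <- ctc_loss(cm, target)
    if (oracle == 0) expect_equal(loss, Inf)
    else expect_equal(exp(-loss), oracle, tolerance = 1e-8)
  }
})

test_that("ctc_loss validates its target", {
  p <- concept_matrix(matrix(1 / 3, 3, 3), c("A", "B"))
  expect_error(ctc_loss(p, c("A", eps)), "blank")
  expect_error(ctc_loss(p, c("A", "Z")), "outside the alphabet")
})

test_that("alignment marginals form a probability distribution", {
  set.seed(7)
  for (i in 1:5) {
    cm <- random_concept_matrix(sample(2:4, 1), 2)
    marg <- enumerate_marginals(cm)
    expect_equal(sum(marg$probability), 1, tolerance = 1e-10)
  }
})

test_that("ctc posterior occupancy rows sum to one", {
  set.seed(3)
  cm <- random_concept_matrix(6, 3)
  fb <- xchar:::ctc_forward_backward(log(unclass(cm)), c(1L, 2L), 4L)
  expect_equal(rowSums(fb$gamma), rep(1, 6), tolerance = 1e-9)
})
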