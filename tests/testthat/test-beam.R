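test_that("beam search returns certain sequences with probability 1", {
  p <- matrix(0, 4, 3)
  p[, 1] <- 1
  cm <- concept_matrix(p, c("A", "B"))
  out <- beam_decode(cm, 5)
  expect_equal(out$sequence, "A")
  expect_equal(out$probability, 1)
})

test_that("marginalization beats the greedy per-step path", {
  # both rows favor blank (0.6) but the two alignments containing A plus
  # A-everywhere sum to 0.64 > 0.36
  cm <- concept_matrix(matrix(c(0.4, 0.4, 0.6, 0.6), 2), "A")
  out <- beam_decode(cm, 4)
  expect_equal(out$sequence, "A")
  expect_equal(out$probability, 0.64, tolerance = 1e-12)
  empty <- Filter(function(b) length(b$sequence) == 0, out$beam)
  expect_equal(empty[[1]]$probability, 0.36, tolerance = 1e-12)
})

test_that("exhaustive-width beam equals enumeration marginalization", {
  set.seed(11)
  for (i in 1:25) {
    m <- sample(1:3, 1)
    t_ <- sample(2:5, 1)
    cm <- random_concept_matrix(t_, m)
    width <- (m + 1)^t_
    out <- beam_decode(cm, width)
    marg <- enumerate_marginals(cm)
    expect_equal(paste(out$sequence, collapse = " "), marg$sequence[1])
    expect_equal(out$probability, marg$probability[1], tolerance = 1e-10)
    # and the whole beam carries the full probability mass
    expect_equal(sum(vapply(out$beam, function(b) b$probability, numeric(1))),
                 1, tolerance = 1e-10)
  }
})

test_that("narrow beams report valid lower bounds, dominated by the exact
           search", {
  set.seed(13)
  for (i in 1:10) {
    cm <- random_concept_matrix(5, 3)
    marg <- enumerate_marginals(cm)
    exact <- beam_decode(cm, 4^5)$probability
    for (w in c(1, 2, 4, 8, 32)) {
      out <- beam_decode(cm, w)
      # the reported mass never exceeds the sequence's true marginal ...
      truth <- marg$probability[marg$sequence ==
                                  paste(out$sequence, collapse = " ")]
      expect_lte(out$probability, truth + 1e-12)
      # ... and the exhaustive search upper-bounds every narrower beam
      expect_lte(out$probability, exact + 1e-12)
    }
  }
})

test_that("beam decoding is deterministic and validates width", {
  cm <- random_concept_matrix(5, 2)
  expect_identical(beam_decode(cm, 8), beam_decode(cm, 8))
  expect_error(beam_decode(cm, 0), "beam_width")
})
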