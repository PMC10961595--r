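test_that("worked distance examples hold", {
  v <- c("V", "C", "G")
  expect_equal(dl_distance(v, v), 0)
  expect_equal(dl_distance(c("A", "B"), c("B", "A")), 1)
  expect_equal(dl_distance(c("A", "B", "C"), c("C", "A", "B")), 2)
  expect_equal(levenshtein(c("A", "B"), c("B", "A")), 2)
  expect_equal(levenshtein("A", character(0)), 1)
  expect_equal(levenshtein(character(0), character(0)), 0)
})

test_that("distances match brute-force edit-script search on short pairs", {
  alphabet <- c("A", "B", "C")
  seqs <- all_sequences(alphabet, 3)
  for (a in seqs[sample.int(length(seqs))][1:12]) {
    bfs_dl <- oracle_edit_bfs(a, alphabet, max_len = 5, transpose = TRUE)
    bfs_lev <- oracle_edit_bfs(a, alphabet, max_len = 5, transpose = FALSE)
    for (b in seqs) {
      k <- oracle_key(b)
      expect_equal(dl_distance(a, b, variant = "dl"), get0(k, envir = bfs_dl),
                   info = sprintf("dl %s | %s", paste(a, collapse = ""),
                                  paste(b, collapse = "")))
      expect_equal(levenshtein(a, b), get0(k, envir = bfs_lev),
                   info = sprintf("lev %s | %s", paste(a, collapse = ""),
                                  paste(b, collapse = "")))
      # the restricted (OSA) variant can only exceed the unrestricted one
      expect_gte(dl_distance(a, b, variant = "osa"),
                 dl_distance(a, b, variant = "dl"))
    }
  }
})

test_that("levenshtein agrees with the independent adist implementation", {
  set.seed(5)
  alphabet <- c("a", "b", "c", "d")
  for (i in 1:200) {
    x <- random_sequence(alphabet, 6)
    y <- random_sequence(alphabet, 6)
    expect_equal(levenshtein(x, y),
                 as.integer(utils::adist(paste(x, collapse = ""),
                                         paste(y, collapse = ""))))
  }
})

test_that("distances behave like metrics on random pairs", {
  set.seed(9)
  alphabet <- LETTERS[1:5]
  for (i in 1:250) {
    x <- random_sequence(alphabet, 5)
    y <- random_sequence(alphabet, 5)
    for (f in list(function(a, b) dl_distance(a, b),
                   levenshtein)) {
      d <- f(x, y)
      expect_gte(d, 0)
      expect_equal(d, f(y, x))
      expect_equal(d == 0, identical(x, y))
      # standard bounds
      expect_gte(d, abs(length(x) - length(y)))
      expect_lte(d, length(x) + length(y))
    }
    # transpositions can only help
    expect_lte(dl_distance(x, y), levenshtein(x, y))
  }
})
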