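# Independent oracles used to validate the package's dynamic programs.

# Exact alignment-marginal of one target: enumerate every path and sum the
# probabilities of those that collapse to the target.
oracle_ctc_prob <- function(cm, target) {
  paths <- enumerate_alignments(target, nrow(cm), utils::head(colnames(cm), -1))
  if (length(paths) == 0) return(0)
  sum(vapply(paths, function(p) {
    prod(cm[cbind(seq_len(nrow(cm)), match(p, colnames(cm)))])
  }, numeric(1)))
}

# Breadth-first search over single edit operations (insert / delete /
# substitute / transpose adjacent) from sequence `a`, over `alphabet`,
# visiting sequences up to length `max_len`; returns minimum script length
# to each reachable sequence as a named vector. This is the unrestricted
# Damerau-Levenshtein distance by definition.
oracle_key <- function(s) paste0("#", paste(s, collapse = ","))

oracle_edit_bfs <- function(a, alphabet, max_len = 6L, transpose = TRUE) {
  key <- oracle_key
  neighbors <- function(s) {
    out <- list()
    n <- length(s)
    if (n < max_len) {
      for (pos in 0:n) for (sym in alphabet) {
        out[[length(out) + 1]] <- append(s, sym, after = pos)
      }
    }
    if (n > 0) {
      for (pos in 1:n) {
        out[[length(out) + 1]] <- s[-pos]
        for (sym in setdiff(alphabet, s[pos])) {
          t <- s; t[pos] <- sym
          out[[length(out) + 1]] <- t
        }
      }
    }
    if (transpose && n > 1) {
      for (pos in 1:(n - 1)) {
        if (s[pos] != s[pos + 1]) {
          t <- s; t[c(pos, pos + 1)] <- t[c(pos + 1, pos)]
          out[[length(out) + 1]] <- t
        }
      }
    }
    out
  }
  dist <- new.env(parent = emptyenv())
  assign(key(a), 0L, envir = dist)
  frontier <- list(a)
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- list()
    for (s in frontier) {
      for (t in neighbors(s)) {
        k <- key(t)
        if (is.null(get0(k, envir = dist))) {
          assign(k, d, envir = dist)
          nxt[[length(nxt) + 1]] <- t
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# All sequences of length 0..max_len over the alphabet.
all_sequences <- function(alphabet, max_len) {
  out <- list(character(0))
  for (k in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), k), list(stringsAsFactors = FALSE)))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i) unname(unlist(grid[i, ]))))
  }
  out
}
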