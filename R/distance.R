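#' Damerau-Levenshtein distance between concept sequences
#'
#' Minimum number of single-concept insertions, deletions, substitutions, or
#' transpositions of two adjacent concepts needed to turn `a` into `b`. The
#' default `"osa"` variant is the restricted optimal-string-alignment dynamic
#' program (no substring is edited twice); `"dl"` is the unrestricted
#' Damerau-Levenshtein distance. The two differ only on contrived inputs
#' (e.g. `CA -> ABC`); both give 1 for one adjacent swap.
#'
#' @param a,b character vectors (possibly empty) over a common alphabet.
#' @param variant `"osa"` (default) or `"dl"`.
#' @return non-negative integer; 0 iff the sequences are equal.
#' @examples
#' dl_distance(c("A", "B"), c("B", "A"))       # 1 (one transposition)
#' dl_distance(c("A", "B", "C"), c("C", "A", "B"))  # 2
#' @export
dl_distance <- function(a, b, variant = c("osa", "dl")) {
  variant <- match.arg(variant)
  a <- as.character(a); b <- as.character(b)
  n <- length(a); m <- length(b)
  if (n == 0) return(m)
  if (m == 0) return(n)
  if (variant == "osa") {
    d <- matrix(0L, n + 1, m + 1)
    d[, 1] <- 0:n
    d[1, ] <- 0:m
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        cost <- if (a[i] == b[j]) 0L else 1L
        v <- min(d[i, j + 1] + 1L,      # deletion
                 d[i + 1, j] + 1L,      # insertion
                 d[i, j] + cost)        # substitution / match
        if (i > 1 && j > 1 && a[i] == b[j - 1] && a[i - 1] == b[j]) {
          v <- min(v, d[i - 1, j - 1] + 1L)   # adjacent transposition
        }
        d[i + 1, j + 1] <- v
      }
    }
    return(as.integer(d[n + 1, m + 1]))
  }
  # unrestricted Damerau-Levenshtein (Lowrance-Wagner)
  alphabet <- unique(c(a, b))
  da <- stats::setNames(rep(0L, length(alphabet)), alphabet)
  maxdist <- n + m
  d <- matrix(0L, n + 2, m + 2)
  d[1, ] <- maxdist
  d[, 1] <- maxdist
  d[2, 2:(m + 2)] <- 0:m
  d[2:(n + 2), 2] <- 0:n
  for (i in seq_len(n)) {
    db <- 0L
    for (j in seq_len(m)) {
      k <- da[[b[j]]]
      l <- db
      if (a[i] == b[j]) {
        cost <- 0L
        db <- j
      } else cost <- 1L
      d[i + 2, j + 2] <- min(
        d[i + 1, j + 1] + cost,                       # substitution
        d[i + 2, j + 1] + 1L,                         # insertion
        d[i + 1, j + 2] + 1L,                         # deletion
        d[k + 1, l + 1] + (i - k - 1L) + 1L + (j - l - 1L)  # transposition
      )
    }
    da[[a[i]]] <- i
  }
  as.integer(d[n + 2, m + 2])
}

#' Levenshtein edit distance between concept sequences
#'
#' Minimum number of insertions, deletions or substitutions (no
#' transposition) transforming `a` into `b`. This is the concept-sequence
#' evaluation metric; counterfactual search uses [dl_distance()] instead,
#' which additionally allows adjacent transpositions.
#'
#' @param a,b character vectors (possibly empty).
#' @return non-negative integer; 0 iff equal.
#' @examples
#' levenshtein(c("A", "B"), c("B", "A"))  # 2; contrast dl_distance() = 1
#' @export
levenshtein <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a); m <- length(b)
  if (n == 0) return(m)
  if (m == 0) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      cur[j + 1] <- min(prev[j + 1] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  as.integer(prev[m + 1])
}
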