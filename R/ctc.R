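#' The blank token
#'
#' CTC augments the concept alphabet with a blank token that stands for
#' "no concept here" (random motion, transitions). It is removed when an
#' alignment path is collapsed to a concept sequence.
#'
#' @return the blank token string.
#' @export
ctc_blank <- function() "<eps>"

#' Per-timestep concept probability matrix
#'
#' Wraps a T' x (M+1) matrix of row-stochastic probabilities: one row per
#' output timestep, one column per concept plus a final column for the blank
#' token.
#'
#' @param probs numeric matrix, rows summing to 1 within 1e-6.
#' @param concepts character vector of M concept identifiers (columns
#'   1..M; the last column is the blank).
#' @return the matrix with class `concept_matrix` and column names set.
#' @export
concept_matrix <- function(probs, concepts) {
  probs <- as.matrix(probs)
  if (ncol(probs) != length(concepts) + 1) {
    stop("matrix must have length(concepts) + 1 columns (last = blank)",
         call. = FALSE)
  }
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("every row must sum to 1 (within 1e-6)", call. = FALSE)
  }
  colnames(probs) <- c(concepts, ctc_blank())
  class(probs) <- c("concept_matrix", class(probs))
  probs
}

cm_concepts <- function(matrix) {
  cn <- colnames(matrix)
  if (is.null(cn)) stop("concept matrix must carry column names", call. = FALSE)
  utils::head(cn, -1)
}

#' Collapse an alignment path to a concept sequence
#'
#' Applies the standard CTC collapse rule: merge consecutive repeats of the
#' same non-blank symbol, then drop all blanks. A blank between two identical
#' concepts therefore separates them into two occurrences.
#'
#' @param path character vector over `concepts` plus the blank token.
#' @param concepts the concept alphabet (for symbol validation); `NULL`
#'   skips validation.
#' @return character vector, possibly empty.
#' @examples
#' collapse_path(c("<eps>", "A", "A", "<eps>", "B"))  # A B
#' collapse_path(c("A", "<eps>", "A"))                # A A
#' @export
collapse_path <- function(path, concepts = NULL) {
  path <- as.character(path)
  if (!is.null(concepts)) {
    unknown <- setdiff(path, c(concepts, ctc_blank()))
    if (length(unknown) > 0) {
      stop("unknown symbol(s) in path: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  if (length(path) == 0) return(character(0))
  r <- rle(path)
  r$values[r$values != ctc_blank()]
}

#' Enumerate all alignments of a target sequence (brute-force oracle)
#'
#' Exhaustively lists every length-`t_prime` path over the blank-augmented
#' alphabet whose collapse equals `target`. Exponential in `t_prime`; intended
#' only as an independent oracle at toy sizes.
#'
#' @param target character vector (concept sequence; may be empty).
#' @param t_prime path length (kept small, <= ~8).
#' @param concepts concept alphabet.
#' @return list of character vectors (possibly empty if infeasible).
#' @export
enumerate_alignments <- function(target, t_prime, concepts) {
  stopifnot(t_prime >= 1)
  symbols <- c(concepts, ctc_blank())
  grid <- do.call(expand.grid,
                  c(rep(list(symbols), t_prime),
                    list(stringsAsFactors = FALSE)))
  keep <- apply(grid, 1, function(p) identical(unname(collapse_path(p)),
                                               as.character(target)))
  lapply(which(keep), function(i) unname(unlist(grid[i, ])))
}

# Minimum path length a target needs: one step per symbol plus one separating
# blank per adjacent repeat.
ctc_min_length <- function(target) {
  k <- length(target)
  if (k == 0) return(0L)
  k + sum(utils::head(target, -1) == utils::tail(target, -1))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# CTC forward-backward in log space over the blank-augmented target.
# logp: T' x (M+1) log-probabilities; target_idx: concept column indices;
# blank: blank column index. Returns the negative log-likelihood and the
# posterior symbol occupancy gamma (T' x (M+1)), whose rows sum to 1.
ctc_forward_backward <- function(logp, target_idx, blank, want_gamma = TRUE) {
  T_ <- nrow(logp)
  k <- length(target_idx)
  U <- 2L * k + 1L
  lab <- integer(U)
  lab[seq(1, U, by = 2)] <- blank
  if (k > 0) lab[seq(2, U, by = 2)] <- target_idx
  # skip transition u-2 -> u allowed when label u is a concept differing
  # from label u-2
  can_skip <- rep(FALSE, U)
  if (U >= 3) {
    for (u in 3:U) can_skip[u] <- lab[u] != blank && lab[u] != lab[u - 2]
  }
  alpha <- matrix(-Inf, T_, U)
  alpha[1, 1] <- logp[1, lab[1]]
  if (U >= 2) alpha[1, 2] <- logp[1, lab[2]]
  if (T_ >= 2) {
    for (t in 2:T_) {
      prev <- alpha[t - 1, ]
      stay <- prev
      from1 <- c(-Inf, prev[-U])
      from2 <- c(-Inf, -Inf, prev[seq_len(U - 2)])
      from2[!can_skip] <- -Inf
      m <- pmax(stay, from1, from2)
      acc <- ifelse(is.finite(m),
                    m + log(exp(stay - m) + exp(from1 - m) + exp(from2 - m)),
                    -Inf)
      alpha[t, ] <- acc + logp[t, lab]
    }
  }
  ll <- if (U >= 2) log_sum_exp(c(alpha[T_, U], alpha[T_, U - 1])) else alpha[T_, U]
  loss <- -ll
  if (!want_gamma || !is.finite(ll)) {
    return(list(loss = loss, gamma = NULL))
  }
  beta <- matrix(-Inf, T_, U)
  beta[T_, U] <- 0
  if (U >= 2) beta[T_, U - 1] <- 0
  if (T_ >= 2) {
    for (t in (T_ - 1):1) {
      nxt <- beta[t + 1, ] + logp[t + 1, lab]
      stay <- nxt
      to1 <- c(nxt[-1], -Inf)
      to2 <- c(nxt[seq.int(3, length.out = max(U - 2, 0))], -Inf, -Inf)
      skip_ok <- c(can_skip[seq.int(3, length.out = max(U - 2, 0))], FALSE, FALSE)
      to2[!skip_ok] <- -Inf
      m <- pmax(stay, to1, to2)
      beta[t, ] <- ifelse(is.finite(m),
                          m + log(exp(stay - m) + exp(to1 - m) + exp(to2 - m)),
                          -Inf)
    }
  }
  # posterior occupancy per augmented label, folded onto alphabet columns
  post <- alpha + beta - ll
  gamma <- matrix(0, T_, ncol(logp))
  for (u in seq_len(U)) {
    w <- exp(post[, u])
    gamma[, lab[u]] <- gamma[, lab[u]] + w
  }
  list(loss = loss, gamma = gamma)
}

#' CTC loss of a target concept sequence
#'
#' The negative log of the total probability of all alignment paths that
#' collapse to `target`, computed by the standard forward dynamic program
#' over the blank-augmented target in log space. Returns `Inf` when no
#' alignment exists (target needs more timesteps than available).
#'
#' @param matrix a [concept_matrix()] (or plain matrix with concept column
#'   names, last column blank).
#' @param target character vector of concepts (must not contain the blank).
#' @return non-negative scalar; `Inf` if the target is infeasible.
#' @examples
#' p <- concept_matrix(matrix(1 / 3, 3, 3), c("A", "B"))
#' ctc_loss(p, c("A", "B"))  # -log(5/27)
#' @export
ctc_loss <- function(matrix, target) {
  concepts <- cm_concepts(matrix)
  target <- as.character(target)
  if (ctc_blank() %in% target) {
    stop("target must not contain the blank token", call. = FALSE)
  }
  unknown <- setdiff(target, concepts)
  if (length(unknown) > 0) {
    stop("target contains concept(s) outside the alphabet: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (ctc_min_length(target) > nrow(matrix)) return(Inf)
  if (length(target) == 0) {
    return(-sum(log(matrix[, ncol(matrix)])))
  }
  logp <- log(pmax(unclass(matrix), 1e-300))
  dim(logp) <- dim(matrix)
  idx <- match(target, concepts)
  ctc_forward_backward(logp, idx, ncol(matrix), want_gamma = FALSE)$loss
}

#' Prefix beam-search decoding of a concept matrix
#'
#' Searches for the most probable concept sequence by extending collapsed
#' prefixes one timestep at a time and merging all alignment paths that share
#' a collapsed prefix (the merge is exactly the marginalization over
#' alignments). With `beam_width` at least the number of reachable prefixes
#' the result is the exact marginal argmax. Ties are broken by higher
#' probability, then shorter sequence, then lexicographic concept order.
#'
#' @param matrix a [concept_matrix()].
#' @param beam_width number of prefixes kept per step (>= 1, default 25).
#' @return list with `sequence` (character), `probability` (marginal, in
#'   (0, 1]), and `beam`: a list of `list(sequence, probability)` ranked
#'   best-first.
#' @examples
#' p <- concept_matrix(matrix(c(0.4, 0.4, 0.6, 0.6), 2), "A")
#' beam_decode(p)$sequence     # "A" (prob 0.64 beats empty at 0.36)
#' @export
beam_decode <- function(matrix, beam_width = 25L) {
  if (beam_width < 1) stop("beam_width must be >= 1", call. = FALSE)
  concepts <- cm_concepts(matrix)
  m <- length(concepts)
  blank <- m + 1L
  T_ <- nrow(matrix)
  # beam state, one row per collapsed prefix:
  #   key      unique string id ("p", "p,3,1", ...)
  #   last     final concept index (0 for the empty prefix)
  #   len      prefix length; sortkey: zero-padded indices for lexicographic
  #            tie-breaking; pb / pnb: mass of paths ending in blank/non-blank
  keys <- "p"; last <- 0L; len <- 0L; sortkey <- ""
  pb <- 1; pnb <- 0
  for (t in seq_len(T_)) {
    p <- matrix[t, ]
    K <- length(keys)
    tot <- pb + pnb
    # candidates that keep the prefix: paths ending in blank, plus repeats of
    # the final concept (run continues)
    rep_p <- ifelse(last > 0L, p[pmax(last, 1L)], 0)
    same_val_b <- tot * p[blank]
    same_val_nb <- pnb * rep_p
    # candidates that extend the prefix by concept s
    parent <- rep(seq_len(K), each = m)
    s_new <- rep(seq_len(m), times = K)
    ext_key <- paste0(keys[parent], ",", s_new)
    # a repeated concept can only follow a blank-terminated path
    ext_val <- ifelse(s_new == last[parent], pb[parent], tot[parent]) * p[s_new]
    cand_key <- c(keys, ext_key)
    uk <- !duplicated(cand_key)
    ukeys <- cand_key[uk]
    pos <- match(cand_key, ukeys)
    npb <- numeric(length(ukeys))
    npnb <- numeric(length(ukeys))
    npb[pos[seq_len(K)]] <- same_val_b
    acc <- rowsum(c(same_val_nb, ext_val), pos, reorder = FALSE)
    npnb[as.integer(rownames(acc))] <- acc[, 1]
    nlast <- c(last, s_new)[uk]
    nlen <- c(len, len[parent] + 1L)[uk]
    nsort <- c(sortkey, paste0(sortkey[parent],
                               sprintf("%04d", s_new)))[uk]
    ord <- order(-(npb + npnb), nlen, nsort)
    keep <- ord[seq_len(min(beam_width, length(ord)))]
    keys <- ukeys[keep]; last <- nlast[keep]; len <- nlen[keep]
    sortkey <- nsort[keep]; pb <- npb[keep]; pnb <- npnb[keep]
  }
  totals <- pb + pnb
  ord <- order(-totals, len, sortkey)
  beam <- lapply(ord, function(i) {
    parts <- strsplit(keys[i], ",", fixed = TRUE)[[1]]
    idx <- if (length(parts) <= 1) integer(0) else as.integer(parts[-1])
    list(sequence = concepts[idx], probability = totals[i])
  })
  list(sequence = beam[[1]]$sequence,
       probability = beam[[1]]$probability,
       beam = beam)
}

#' Exact marginal distribution over collapsed sequences (oracle)
#'
#' Enumerates every alignment path of length T' and accumulates path
#' probabilities by collapsed sequence. Exponential; oracle use only.
#'
#' @param matrix a [concept_matrix()] with small T'.
#' @return data.frame with columns `sequence` (collapsed, " "-joined) and
#'   `probability`, sorted by decreasing probability.
#' @export
enumerate_marginals <- function(matrix) {
  concepts <- cm_concepts(matrix)
  symbols <- c(concepts, ctc_blank())
  T_ <- nrow(matrix)
  grid <- do.call(expand.grid,
                  c(rep(list(seq_along(symbols)), T_),
                    list(stringsAsFactors = FALSE)))
  probs <- apply(grid, 1, function(idx) prod(matrix[cbind(seq_len(T_), idx)]))
  seqs <- apply(grid, 1, function(idx) {
    paste(collapse_path(symbols[unlist(idx)]), collapse = " ")
  })
  agg <- tapply(probs, seqs, sum)
  out <- data.frame(sequence = names(agg), probability = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out[order(-out$probability, nchar(out$sequence), out$sequence), , drop = FALSE]
}
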