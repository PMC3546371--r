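# Permutation generators: complete lexicographic enumeration with
# rank/unrank (O(1)-equivalent forwarding) and a counter-based random
# stream.  Both expose the same contract: element 0 of a stream is the
# observed labelling, element i depends only on (seed, i, observed,
# structure), so any contiguous chunk can be produced independently on
# any worker and chunked runs reduce to exactly the serial stream.

.STRUCTURES <- c("two_group", "k_group", "paired", "blocked")

# exact multinomial coefficient n! / prod(counts!)
.multinomial <- function(counts) {
  n <- sum(counts)
  out <- 1
  for (c in counts) {
    out <- out * choose(n, c)
    n <- n - c
  }
  out
}

#' Size of the complete enumeration for a label structure
#'
#' Two groups: `choose(n, n1)` distinct assignments; k groups: the
#' multinomial coefficient; paired: `2^npairs` within-pair swaps;
#' blocked: `(k!)^nblocks` within-block rearrangements.
#'
#' @param labels Integer label vector (the observed labelling).
#' @param structure One of `"two_group"`, `"k_group"`, `"paired"`,
#'   `"blocked"`.
#' @return The enumeration size as a double (exact while below 2^53).
#' @examples
#' count_complete(rep(c(0, 1), each = 4), "two_group")  # choose(8,4) = 70
#' @export
count_complete <- function(labels, structure = "two_group") {
  structure <- match.arg(structure, .STRUCTURES)
  labels <- validate_labels(labels, structure)
  n <- length(labels)
  switch(structure,
         two_group = choose(n, sum(labels == 1L)),
         k_group = .multinomial(tabulate(labels + 1L)),
         paired = 2^(n / 2),
         blocked = factorial(max(labels) + 1L)^(n / (max(labels) + 1L)))
}

# --- multiset permutation rank/unrank (lexicographic over label
#     sequences; labels compare as integers) -------------------------

.unrank_multiset <- function(rank, counts) {
  n <- sum(counts)
  N <- .multinomial(counts)
  out <- integer(n)
  for (pos in seq_len(n)) {
    for (v in which(counts > 0L)) {
      cnt <- round(N * counts[v] / n)      # sequences starting with label v-1
      if (rank < cnt) {
        out[pos] <- v - 1L
        counts[v] <- counts[v] - 1L
        N <- cnt
        break
      }
      rank <- rank - cnt
    }
    n <- n - 1L
  }
  out
}

.rank_multiset <- function(labels, counts) {
  n <- sum(counts)
  N <- .multinomial(counts)
  rank <- 0
  for (pos in seq_along(labels)) {
    v0 <- labels[pos] + 1L
    for (v in which(counts > 0L)) {
      cnt <- round(N * counts[v] / n)
      if (v == v0) {
        counts[v] <- counts[v] - 1L
        N <- cnt
        break
      }
      rank <- rank + cnt
    }
    n <- n - 1L
  }
  rank
}

# --- permutation-of-0..k-1 (Lehmer) rank/unrank for one block --------

.unrank_perm <- function(rank, k) {
  avail <- 0:(k - 1L)
  out <- integer(k)
  for (pos in seq_len(k)) {
    f <- factorial(k - pos)
    i <- rank %/% f
    rank <- rank %% f
    out[pos] <- avail[i + 1L]
    avail <- avail[-(i + 1L)]
  }
  out
}

.rank_perm <- function(perm) {
  k <- length(perm)
  avail <- 0:(k - 1L)
  rank <- 0
  for (pos in seq_len(k)) {
    i <- match(perm[pos], avail) - 1L
    rank <- rank + i * factorial(k - pos)
    avail <- avail[-(i + 1L)]
  }
  rank
}

#' Lexicographic rank of a label assignment
#'
#' Inverse of [unrank_assignment()]: position of an admissible labelling
#' in the canonical lexicographic enumeration of its structure.
#'
#' @inheritParams count_complete
#' @return Zero-based rank as a double.
#' @export
rank_assignment <- function(labels, structure = "two_group") {
  structure <- match.arg(structure, .STRUCTURES)
  labels <- validate_labels(labels, structure)
  switch(structure,
    two_group = .rank_multiset(labels, tabulate(labels + 1L)),
    k_group = .rank_multiset(labels, tabulate(labels + 1L)),
    paired = {
      bits <- labels[seq(1L, length(labels), by = 2L)]  # 1 -> pair (1,0)
      sum(bits * 2^(rev(seq_along(bits)) - 1L))
    },
    blocked = {
      k <- max(labels) + 1L
      blocks <- matrix(labels, nrow = k)
      ranks <- apply(blocks, 2L, .rank_perm)
      sum(ranks * factorial(k)^(rev(seq_along(ranks)) - 1L))
    })
}

#' Label assignment at a given lexicographic rank
#'
#' Produces the `rank`-th element (zero-based) of the canonical
#' lexicographic enumeration of the structure's assignment space: label
#' sequences for the group structures, binary counting over within-pair
#' swaps (pair 0 most significant), and mixed-radix counting over
#' per-block Lehmer ranks.  Bijective with [rank_assignment()].
#'
#' @param rank Zero-based rank, `0 <= rank < count_complete(...)`.
#' @inheritParams count_complete
#' @return Integer label vector.
#' @examples
#' unrank_assignment(0, c(0L, 1L, 0L, 1L), "two_group")  # 0 0 1 1
#' @export
unrank_assignment <- function(rank, labels, structure = "two_group") {
  structure <- match.arg(structure, .STRUCTURES)
  labels <- validate_labels(labels, structure)
  N <- count_complete(labels, structure)
  if (N > 2^53) stop("enumeration too large to index exactly")
  if (rank < 0 || rank >= N) stop("rank out of range [0, ", N, ")")
  n <- length(labels)
  switch(structure,
    two_group = .unrank_multiset(rank, tabulate(labels + 1L)),
    k_group = .unrank_multiset(rank, tabulate(labels + 1L)),
    paired = {
      np <- n %/% 2L
      bits <- (rank %/% 2^(np - seq_len(np))) %% 2
      as.integer(rbind(bits, 1 - bits))
    },
    blocked = {
      k <- max(labels) + 1L
      nb <- n %/% k
      f <- factorial(k)
      ranks <- (rank %/% f^(nb - seq_len(nb))) %% f
      as.integer(vapply(ranks, .unrank_perm, integer(k), k = k))
    })
}

#' Chunk of the complete permutation stream
#'
#' Stream element 0 is the observed labelling; elements `1..B-1` walk
#' the lexicographic enumeration with the observed labelling's own slot
#' omitted, so every admissible assignment occurs exactly once in the
#' full stream of length `B = count_complete(...)`.
#'
#' @param labels Observed labelling.
#' @inheritParams count_complete
#' @param skip First stream index to produce (0-based).
#' @param count Number of consecutive elements.
#' @return Integer matrix, one column per stream element.
#' @export
complete_stream <- function(labels, structure = "two_group",
                            skip = 0, count = 1) {
  structure <- match.arg(structure, .STRUCTURES)
  labels <- validate_labels(labels, structure)
  B <- count_complete(labels, structure)
  if (skip < 0 || count < 0 || skip + count > B)
    stop("requested chunk [", skip, ", ", skip + count,
         ") exceeds the stream length ", B)
  r_obs <- rank_assignment(labels, structure)
  out <- matrix(NA_integer_, nrow = length(labels), ncol = count)
  for (t in seq_len(count)) {
    i <- skip + t - 1
    out[, t] <- if (i == 0) labels
                else unrank_assignment(i - 1 + (i - 1 >= r_obs),
                                       labels, structure)
  }
  out
}

#' Chunk of the random (Monte Carlo) permutation stream
#'
#' Stream element 0 is the observed labelling; element `i >= 1` is drawn
#' uniformly over the structure's assignment space (with replacement
#' across elements) by a counter-based generator keyed on `(seed, i)`.
#' Any chunking of indices therefore reproduces the serial stream
#' exactly.
#'
#' @inheritParams complete_stream
#' @param seed Integer stream seed.
#' @return Integer matrix, one column per stream element.
#' @export
random_stream <- function(labels, structure = "two_group", seed = 0,
                          skip = 0, count = 1) {
  structure <- match.arg(structure, .STRUCTURES)
  labels <- validate_labels(labels, structure)
  n <- length(labels)
  if (skip < 0 || count < 0) stop("skip and count must be non-negative")
  out <- matrix(NA_integer_, nrow = n, ncol = count)
  if (count == 0) return(out)
  idx <- seq.int(skip, length.out = count)
  if (idx[1L] == 0) out[, 1L] <- labels
  cols <- which(idx >= 1)
  if (!length(cols)) return(out)
  draw_idx <- idx[cols]
  if (structure %in% c("two_group", "k_group")) {
    U <- .keyed_uniforms(seed, draw_idx, n)
    for (t in seq_along(cols))
      out[, cols[t]] <- labels[order(U[t, ])]
  } else if (structure == "paired") {
    np <- n %/% 2L
    U <- .keyed_uniforms(seed, draw_idx, np)
    for (t in seq_along(cols)) {
      bits <- as.integer(U[t, ] < 0.5)        # 1 -> pair (1,0)
      out[, cols[t]] <- as.integer(rbind(bits, 1L - bits))
    }
  } else {                                    # blocked
    k <- max(labels) + 1L
    nb <- n %/% k
    U <- .keyed_uniforms(seed, draw_idx, n)
    base <- 0:(k - 1L)
    for (t in seq_along(cols)) {
      lab <- integer(n)
      for (b in seq_len(nb)) {
        pos <- (b - 1L) * k + seq_len(k)
        lab[pos] <- base[order(U[t, pos])]
      }
      out[, cols[t]] <- lab
    }
  }
  out
}

# unified stream used by the engine
.stream_chunk <- function(labels, structure, mode, seed, skip, count) {
  if (mode == "complete") complete_stream(labels, structure, skip, count)
  else random_stream(labels, structure, seed, skip, count)
}
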