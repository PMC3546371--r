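# Permutation generators: enumeration sizes, lexicographic
# rank/unrank, identity-first streams, chunk invariance and uniformity.

lab44 <- rep(c(0L, 1L), each = 4)
lab_pair5 <- rep(c(0L, 1L), 5)
lab_block33 <- rep(0:2, 3)
lab_k222 <- rep(0:2, each = 2)

key_of <- function(M) apply(M, 2, paste, collapse = "")

test_that("complete enumeration sizes follow the design combinatorics", {
  expect_equal(count_complete(lab44, "two_group"), 70)
  expect_equal(count_complete(lab_pair5, "paired"), 32)
  expect_equal(count_complete(lab_block33, "blocked"), 216)
  expect_equal(count_complete(lab_k222, "k_group"), 90)
})

test_that("unranking is lexicographic and bijective", {
  l4 <- c(0L, 1L, 0L, 1L)
  expect_equal(unrank_assignment(0, l4), c(0L, 0L, 1L, 1L))  # group 0 at {0,1}
  expect_equal(unrank_assignment(5, l4), c(1L, 1L, 0L, 0L))  # group 0 at {2,3}
  for (cfg in list(list(lab44, "two_group"),
                   list(lab_pair5, "paired"),
                   list(lab_block33, "blocked"),
                   list(lab_k222, "k_group"))) {
    N <- count_complete(cfg[[1]], cfg[[2]])
    ranks <- vapply(seq_len(N) - 1, function(r)
      rank_assignment(unrank_assignment(r, cfg[[1]], cfg[[2]]), cfg[[2]]),
      numeric(1))
    expect_equal(ranks, seq_len(N) - 1)
  }
  expect_error(unrank_assignment(70, lab44), "out of range")
})

test_that("complete streams start at the observed labelling and enumerate each assignment once", {
  obs <- c(0L, 1L, 1L, 0L, 0L, 1L)        # not the lexicographic first
  expect_identical(complete_stream(obs, "two_group", 0, 1)[, 1], obs)
  full <- complete_stream(obs, "two_group", 0, 20)
  ref <- apply(combn(6, 3), 2, function(p) {
    l <- rep(1L, 6); l[p] <- 0L; l
  })
  expect_setequal(key_of(full), key_of(ref))
  expect_equal(anyDuplicated(key_of(full)), 0)
  # chunk concatenation equals the contiguous chunk
  expect_identical(cbind(complete_stream(obs, "two_group", 0, 3),
                         complete_stream(obs, "two_group", 3, 4)),
                   complete_stream(obs, "two_group", 0, 7))
  expect_error(complete_stream(obs, "two_group", 15, 10), "exceeds")
})

test_that("complete streams cover paired and blocked spaces exactly once", {
  sp <- complete_stream(lab_pair5, "paired", 0, 32)
  expect_equal(anyDuplicated(key_of(sp)), 0)
  expect_identical(sp[, 1], lab_pair5)
  for (j in seq_len(32)) validate_labels(sp[, j], "paired")
  sb <- complete_stream(lab_block33, "blocked", 0, 216)
  expect_equal(anyDuplicated(key_of(sb)), 0)
  for (j in seq_len(216)) validate_labels(sb[, j], "blocked")
})

test_that("random streams are identity-first, keyed by index and chunking invariant", {
  for (cfg in list(list(lab44, "two_group"),
                   list(lab_pair5, "paired"),
                   list(lab_block33, "blocked"))) {
    obs <- cfg[[1]]; st <- cfg[[2]]
    expect_identical(random_stream(obs, st, seed = 9, 0, 1)[, 1], obs)
    full <- random_stream(obs, st, seed = 9, 0, 12)
    part <- random_stream(obs, st, seed = 9, 5, 5)
    expect_identical(part, full[, 6:10])
    pieces <- cbind(random_stream(obs, st, seed = 9, 0, 4),
                    random_stream(obs, st, seed = 9, 4, 3),
                    random_stream(obs, st, seed = 9, 7, 5))
    expect_identical(pieces, full)
    for (j in 2:12) validate_labels(full[, j], st)
    # a different seed gives a different stream
    expect_false(identical(random_stream(obs, st, seed = 10, 1, 8),
                           random_stream(obs, st, seed = 9, 1, 8)))
  }
})

test_that("random draws are uniform over a small assignment space", {
  l4 <- c(0L, 0L, 1L, 1L)
  draws <- random_stream(l4, "two_group", seed = 3, 1, 3000)
  ref <- complete_stream(l4, "two_group", 0, 6)
  counts <- table(factor(key_of(draws), levels = key_of(ref)))
  expect_true(all(counts > 0))
  expect_gt(chisq.test(counts)$p.value, 0.001)
})
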