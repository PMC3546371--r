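# The step-down engine: ordering, successive maxima, counting,
# reduction and finalization, checked against forced examples and the
# brute-force oracle.

test_that("order_genes sorts by decreasing extremeness with stable ties and NA tail", {
  expect_equal(order_genes(c(1, 3, 2))$order, c(2, 3, 1))
  o <- order_genes(c(2, 2))
  expect_equal(o$order, c(1, 2))                   # tie -> input order
  o <- order_genes(c(1, NA, 2))
  expect_equal(o$order, c(3, 1, 2))
  expect_equal(o$defined_count, 2)
  expect_error(order_genes(c(NA_real_, NA_real_)), "undefined")
})

test_that("successive maxima follow the backward max recursion", {
  ordering <- order_genes(c(1, 3, 2))              # ranks: g2, g3, g1
  expect_equal(successive_maxima(c(0.5, 2, 1), ordering), c(2, 1, 0.5))
  expect_equal(successive_maxima(c(7, 7, 7), ordering), c(7, 7, 7))
  set.seed(11)
  for (i in 1:25) {
    e <- rnorm(8)
    u <- successive_maxima(rnorm(8), order_genes(e))
    expect_true(all(diff(u) <= 0))                 # nonincreasing in rank
  }
})

test_that("the identity labelling always counts for every defined gene", {
  d <- toy_two_group()
  acc <- accumulate_chunk(d$X, matrix(d$classlabel), d$classlabel)
  s <- compute_statistics(d$X, d$classlabel)
  expect_equal(acc$raw_counts[s$defined], rep(1, sum(s$defined)))
  expect_equal(acc$raw_counts[!s$defined], rep(0, sum(!s$defined)))
  expect_equal(acc$adj_counts[seq_len(sum(s$defined))],
               rep(1, sum(s$defined)))
  expect_equal(acc$processed, 1)
})

test_that("identical genes accumulate identical raw counts", {
  set.seed(12)
  x <- rnorm(8)
  X <- rbind(a = x, b = x, c = rnorm(8))
  lab <- rep(c(0L, 1L), each = 4)
  chunk <- complete_stream(lab, "two_group", 0, 70)
  acc <- accumulate_chunk(X, chunk, lab)
  expect_identical(acc$raw_counts[1], acc$raw_counts[2])
})

test_that("accumulators reduce by order-independent integer sums", {
  d <- toy_two_group()
  lab <- d$classlabel
  c1 <- accumulate_chunk(d$X, complete_stream(lab, "two_group", 0, 30), lab)
  c2 <- accumulate_chunk(d$X, complete_stream(lab, "two_group", 30, 40), lab)
  whole <- accumulate_chunk(d$X, complete_stream(lab, "two_group", 0, 70), lab)
  expect_identical(reduce_accumulators(list(c1, c2)), whole)
  expect_identical(reduce_accumulators(list(c2, c1))$raw_counts,
                   whole$raw_counts)
  expect_identical(reduce_accumulators(list(whole)), whole)
})

test_that("finalization enforces monotone adjusted p-values and the 1/B floor", {
  ordering <- list(order = 1:3, defined_count = 3L)
  acc <- list(raw_counts = c(2, 1, 3), adj_counts = c(2, 1, 3),
              processed = 10)
  res <- finalize_pvalues(acc, ordering, teststat = c(3, 2, 1))
  expect_equal(res$adjp, c(0.2, 0.2, 0.3))
  expect_equal(res$rawp, c(0.2, 0.1, 0.3))
  # B = 1 (identity only): every defined p-value is 1
  d <- toy_two_group()
  r1 <- pmaxt(d$X, d$classlabel, B = 1)
  defined <- !is.na(r1$rawp)
  expect_true(all(r1$rawp[defined] == 1))
  expect_true(all(r1$adjp[defined] == 1))
})

test_that("a single gene collapses adjusted to raw p-values", {
  set.seed(13)
  X <- matrix(rnorm(8), 1, dimnames = list("g1"))
  lab <- rep(c(0L, 1L), each = 4)
  res <- pmaxt(X, lab, B = 0)
  expect_identical(res$adjp, res$rawp)
  # strongly separated single gene, upper side: observed is the unique
  # maximum over all 70 relabelings
  Xs <- matrix(c(10, 11, 12, 13, 0, 1, 2, 3), 1)
  rs <- pmaxt(Xs, lab, B = 0, side = "upper")
  expect_equal(rs$rawp, 1 / 70)
})

test_that("engine equals the brute-force oracle on a toy two-group instance", {
  d <- toy_two_group()
  res <- pmaxt(d$X, d$classlabel, test = "t", side = "abs", B = 0)
  bf <- brute_force_maxt(d$X, d$classlabel, test = "t", side = "abs")
  expect_identical(res$gene_id, bf$gene_id)
  expect_equal(res$rawp, bf$rawp)
  expect_equal(res$adjp, bf$adjp)
  expect_equal(res$teststat, bf$teststat, tolerance = 1e-12)
})

test_that("undefined observed statistics are reported missing, at the tail", {
  d <- toy_two_group()                      # row 3 constant -> undefined
  res <- pmaxt(d$X, d$classlabel, B = 0)
  expect_equal(res$gene_id[nrow(res)], "g03")
  expect_true(is.na(res$rawp[nrow(res)]))
  expect_true(is.na(res$adjp[nrow(res)]))
  expect_true(all(!is.na(res$rawp[-nrow(res)])))
})
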