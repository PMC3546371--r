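# The six statistics against independent textbook/model-fit oracles,
# their degenerate cases, and the structural invariants of the
# statistic layer.

test_that("two-sample statistics match their textbook oracles on random draws", {
  set.seed(101)
  for (i in 1:20) {
    a <- rnorm(sample(2:6, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(2:6, 1), mean = runif(1, -1, 1))
    expect_equal(welch_t(a, b), oracle_welch(a, b), tolerance = 1e-12)
    expect_equal(t_equalvar(a, b), oracle_pooled(a, b), tolerance = 1e-12)
    expect_equal(wilcoxon_std(a, b), oracle_wilcoxon_z(a, b),
                 tolerance = 1e-12)
  }
  # frozen worked example for the Welch formula
  expect_equal(welch_t(c(4.1, 5.2, 6.0), c(1.0, 2.2)),
               oracle_welch(c(4.1, 5.2, 6.0), c(1.0, 2.2)),
               tolerance = 1e-12)
})

test_that("two-sample statistics handle symmetry and degeneracy", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(t_equalvar(c(1, 2), c(1, 2)), 0)
  expect_true(is.na(welch_t(c(0, 0), c(1, 1))))    # both variances zero
  expect_true(is.na(t_equalvar(c(2, 2), c(5, 5))))
  expect_true(is.na(welch_t(1, c(1, 2, 3))))       # < 2 per group
  # equal sizes and equal sample variances: Welch == pooled
  a <- c(0, 1, 2); b <- c(5, 6, 7)
  expect_equal(welch_t(a, b), t_equalvar(a, b), tolerance = 1e-12)
})

test_that("wilcoxon uses midranks and centers at its expectation", {
  # identical multisets split evenly: W = E[W] so z = 0
  expect_equal(wilcoxon_std(c(1, 2, 3), c(3, 1, 2)), 0)
  # sum of z over all relabelings is 0 for tie-free data
  x <- c(0.3, 1.7, 2.2, 4.1)
  z <- apply(combn(4, 2), 2, function(p)
    wilcoxon_std(x[p], x[-p]))
  expect_equal(sum(z), 0, tolerance = 1e-12)
})

test_that("anova F matches aov and reduces to t_equalvar squared at k = 2", {
  set.seed(102)
  for (i in 1:10) {
    groups <- lapply(1:3, function(j) rnorm(3, mean = j / 2))
    expect_equal(anova_f(groups), oracle_f(groups), tolerance = 1e-10)
  }
  a <- rnorm(5); b <- rnorm(4, 1)
  expect_equal(anova_f(list(a, b)), t_equalvar(a, b)^2, tolerance = 1e-10)
  # equal group means with nonzero within-group variation: F = 0
  expect_equal(anova_f(list(c(-1, 1), c(-2, 2))), 0)
  # no within-group variation: undefined
  expect_true(is.na(anova_f(list(c(1, 1), c(2, 2)))))
})

test_that("paired t matches t.test and handles degenerate differences", {
  set.seed(103)
  for (i in 1:10) {
    tr <- rnorm(5, 0.5); ct <- rnorm(5)
    expect_equal(paired_t(cbind(tr, ct)), oracle_pairt(tr, ct),
                 tolerance = 1e-12)
  }
  expect_true(is.na(paired_t(cbind(c(1, 2, 3), c(1, 2, 3)))))  # all d = 0
  d <- c(1, -1, 1, -1)
  expect_equal(paired_t(cbind(d, rep(0, 4))), 0)               # dbar = 0
})

test_that("block F matches the two-way ANOVA oracle and is shift invariant", {
  set.seed(104)
  for (i in 1:10) {
    tab <- matrix(rnorm(9), 3, 3) + outer(rnorm(3, sd = 2), c(0, 0.5, 1), `+`)
    expect_equal(block_f(tab), oracle_blockf(tab), tolerance = 1e-10)
    # adding a constant to a whole block leaves F unchanged
    tab2 <- tab + c(5, -3, 11)
    expect_equal(block_f(tab2), block_f(tab), tolerance = 1e-8)
  }
  # treatment effect absent but residual present: F = 0 exactly requires
  # equal treatment means
  tab <- rbind(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  expect_equal(block_f(tab), 0, tolerance = 1e-12)
  # constant within blocks: all variation is block variation, residual 0
  expect_true(is.na(block_f(matrix(c(1, 1, 1, 5, 5, 5), 2, 3, byrow = TRUE))))
})

test_that("rank transform produces midranks and preserves missingness", {
  expect_equal(rank_transform(c(3.1, 1.0, 2.0)), c(3, 1, 2))
  expect_equal(rank_transform(c(1, 1, 2)), c(1.5, 1.5, 3))
  expect_equal(rank_transform(c(5, NA, 1)), c(2, NA, 1))
})

test_that("side transform flips and folds consistently", {
  d <- toy_two_group()
  up <- compute_statistics(d$X, d$classlabel, test = "t", side = "upper")
  lo <- compute_statistics(d$X, d$classlabel, test = "t", side = "lower")
  ab <- compute_statistics(d$X, d$classlabel, test = "t", side = "abs")
  expect_equal(lo$extreme, -up$extreme)
  expect_equal(ab$extreme, abs(up$extreme))
  expect_equal(up$teststat, lo$teststat)  # reported statistic is signed
})

test_that("statistics are equivariant under joint column/label permutation", {
  d <- toy_two_group(with_degenerate = FALSE)
  set.seed(105)
  for (test in c("t", "wilcoxon", "f")) {
    lab <- if (test == "f") rep(0:1, each = 4) else d$classlabel
    s0 <- compute_statistics(d$X, lab, test = test)$teststat
    perm <- sample(ncol(d$X))
    s1 <- compute_statistics(d$X[, perm], lab[perm], test = test)$teststat
    expect_equal(s1, s0, tolerance = 1e-12)
  }
})

test_that("a missing value behaves exactly like a deleted sample for that gene", {
  set.seed(106)
  x <- rnorm(8)
  lab <- rep(c(0L, 1L), each = 4)
  for (drop in c(2, 7)) {
    xm <- x; xm[drop] <- -999
    s <- compute_statistics(matrix(xm, 1), lab, test = "t",
                            na = -999)$teststat
    expect_equal(s, welch_t(x[lab == 0 & seq_along(x) != drop],
                            x[lab == 1 & seq_along(x) != drop]),
                 tolerance = 1e-12)
  }
  # other genes are untouched
  X <- matrix(rnorm(16), 2, 8)
  Xm <- X; Xm[1, 3] <- NA
  s_full <- compute_statistics(X, lab, test = "t")$teststat
  s_miss <- compute_statistics(Xm, lab, test = "t")$teststat
  expect_identical(s_miss[2], s_full[2])
})

test_that("nonpara = 'y' is the midrank transform before the statistic", {
  d <- toy_two_group(with_degenerate = FALSE, with_missing = FALSE)
  s_np <- compute_statistics(d$X, d$classlabel, test = "t",
                             nonpara = "y")$teststat
  R <- t(apply(d$X, 1, rank))
  s_rk <- compute_statistics(R, d$classlabel, test = "t")$teststat
  expect_equal(s_np, s_rk)
})

test_that("structure/label mismatches raise configuration errors", {
  X <- matrix(rnorm(16), 2, 8)
  expect_error(compute_statistics(X, rep(0L, 8), test = "t"),
               "labels 0 and 1")
  expect_error(compute_statistics(X, c(0, 1, 2, 0, 1, 2, 0, 1),
                                  test = "blockf"), "block")
  expect_error(compute_statistics(X, rep(c(0L, 1L), 4), test = "t",
                                  side = "sideways"))
})
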