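# Independent textbook oracles, all through base R model-fitting code,
# against which the compiled statistics are checked.

oracle_welch <- function(a, b) unname(t.test(a, b)$statistic)

oracle_pooled <- function(a, b)
  unname(t.test(a, b, var.equal = TRUE)$statistic)

oracle_wilcoxon_z <- function(a, b) {
  r <- rank(c(a, b))
  n0 <- length(a); n1 <- length(b); n <- n0 + n1
  (sum(r[seq_len(n0)]) - n0 * (n + 1) / 2) / sqrt(n0 * n1 * (n + 1) / 12)
}

oracle_f <- function(groups) {
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  unname(summary(stats::aov(y ~ g))[[1]][["F value"]][1L])
}

oracle_pairt <- function(treated, control)
  unname(t.test(treated, control, paired = TRUE)$statistic)

oracle_blockf <- function(tab) {   # one row per block, one col per treatment
  y <- as.vector(tab)
  block <- factor(as.vector(row(tab)))
  treat <- factor(as.vector(col(tab)))
  unname(stats::anova(stats::lm(y ~ block + treat))["treat", "F value"])
}

# small labelled dataset builders -------------------------------------

toy_two_group <- function(m = 12, n0 = 4, n1 = 4, seed = 42,
                          with_missing = TRUE, with_degenerate = TRUE) {
  set.seed(seed)
  n <- n0 + n1
  X <- matrix(rnorm(m * n), m, n,
              dimnames = list(sprintf("g%02d", seq_len(m)), NULL))
  X[1, n0 + seq_len(n1)] <- X[1, n0 + seq_len(n1)] + 2.5
  if (with_missing) X[2, c(1, n0 + 1)] <- NA
  if (with_degenerate) X[3, ] <- 1        # constant row: t undefined
  list(X = X, classlabel = rep(c(0L, 1L), c(n0, n1)))
}
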