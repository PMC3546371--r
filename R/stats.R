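# Test-statistic surface: the six statistics, the midrank transform and
# the per-gene statistic vector with missing-value exclusion and side
# transformation.

.TEST_CODES <- c(t = 0L, t.equalvar = 1L, wilcoxon = 2L,
                 f = 3L, pairt = 4L, blockf = 5L)
.SIDE_CODES <- c(abs = 0L, upper = 1L, lower = 2L)

#' Label structure implied by a test
#'
#' Maps each statistic to the class-label structure it permutes over:
#' two groups for the two-sample statistics, k groups for the one-way F,
#' consecutive (control, treated) pairs for the paired t and consecutive
#' blocks of one observation per treatment for the block F.
#'
#' @param test One of `"t"`, `"t.equalvar"`, `"wilcoxon"`, `"f"`,
#'   `"pairt"`, `"blockf"`.
#' @return One of `"two_group"`, `"k_group"`, `"paired"`, `"blocked"`.
#' @export
test_structure <- function(test) {
  test <- match.arg(test, names(.TEST_CODES))
  switch(test,
         t = , t.equalvar = , wilcoxon = "two_group",
         f = "k_group",
         pairt = "paired",
         blockf = "blocked")
}

# number of label levels a design carries (block size for blockf)
.design_k <- function(labels, structure) {
  switch(structure,
         two_group = 2L,
         paired = 2L,
         k_group = max(labels) + 1L,
         blocked = max(labels) + 1L)
}

#' Validate a class-label vector against a label structure
#'
#' @param labels Integer vector of per-sample class labels.
#' @param structure One of `"two_group"`, `"k_group"`, `"paired"`,
#'   `"blocked"`.
#' @return The labels, as integers, invisibly usable downstream.
#' @export
validate_labels <- function(labels, structure) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n < 2L) stop("at least two samples are required")
  if (anyNA(labels)) stop("class labels must not contain NA")
  switch(structure,
    two_group = {
      if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) != 2L)
        stop("two-group tests require labels 0 and 1, both present")
    },
    k_group = {
      k <- max(labels) + 1L
      if (min(labels) < 0L || k < 2L || !all(0:(k - 1L) %in% labels))
        stop("k-group tests require labels 0..k-1, all present")
    },
    paired = {
      if (n %% 2L != 0L)
        stop("paired test requires an even number of samples")
      odd <- labels[seq(1L, n, by = 2L)]
      even <- labels[seq(2L, n, by = 2L)]
      if (!all(odd + even == 1L) || !all(labels %in% c(0L, 1L)))
        stop("paired test requires each consecutive column pair to contain one 0 and one 1")
    },
    blocked = {
      k <- max(labels) + 1L
      if (k < 2L || n %% k != 0L)
        stop("block test requires the sample count to be a multiple of the block size")
      blocks <- matrix(labels, nrow = k)
      if (!all(apply(blocks, 2L, function(b) identical(sort(b), 0:(k - 1L)))))
        stop("block test requires each consecutive block of k columns to contain each label 0..k-1 exactly once")
    },
    stop("unknown label structure: ", structure)
  )
  labels
}

#' Replace values by midranks
#'
#' Non-missing values are replaced by their midranks (ties get the
#' average of the ranks they would occupy); missing values are kept
#' missing.
#'
#' @param x Numeric vector, possibly with `NA`.
#' @return Numeric vector of midranks with `NA` preserved.
#' @export
rank_transform <- function(x) {
  rank(x, na.last = "keep", ties.method = "average")
}

# midrank-transform every row of a matrix, preserving NA
.rank_rows <- function(X) {
  t(apply(X, 1L, rank_transform))
}

# recode the missing-value sentinel and check basic matrix invariants
.prepare_matrix <- function(X, na = NA) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!is.na(na)) X[!is.na(X) & X == na] <- NA_real_
  if (nrow(X) < 1L || ncol(X) < 2L)
    stop("expression matrix must have at least 1 gene and 2 samples")
  if (any(rowSums(!is.na(X)) == 0L))
    stop("every gene must have at least one non-missing value")
  X
}

# apply the rejection-side transform; NA (undefined) stays NA here
.side_transform <- function(s, side) {
  switch(side, abs = abs(s), upper = s, lower = -s)
}

#' Per-gene test statistics under one labelling
#'
#' Computes the chosen statistic for every gene on its non-missing
#' values.  With `nonpara = "y"` each gene's non-missing values are
#' first replaced by midranks (the Wilcoxon statistic always works on
#' midranks).  The side transform is applied so that larger values of
#' the `extreme` component always mean more extreme: `abs` takes
#' absolute values, `upper` keeps the sign, `lower` negates.
#'
#' Genes with too few usable values (fewer than 2 non-missing values per
#' group for the t statistics, fewer than 2 represented groups for F,
#' fewer than 2 complete pairs or blocks) get an undefined statistic,
#' flagged rather than aborting the run.
#'
#' @param X Numeric genes x samples matrix; missing values either `NA`
#'   or equal to the `na` sentinel.
#' @param classlabel Integer per-sample labels consistent with the test.
#' @param test Statistic: `"t"` (Welch), `"t.equalvar"`, `"wilcoxon"`,
#'   `"f"`, `"pairt"` or `"blockf"`.
#' @param side Rejection side: `"abs"`, `"upper"` or `"lower"`.
#' @param nonpara `"y"` to midrank-transform each gene first, else `"n"`.
#' @param na Numeric missing-value code, or `NA` if the matrix already
#'   uses `NA`.
#' @return A list with components `teststat` (signed statistics, `NA`
#'   where undefined), `extreme` (side-transformed statistics) and
#'   `defined` (logical mask).
#' @examples
#' X <- rbind(g1 = c(4.1, 5.2, 6.0, 1.0, 2.2, 3.1))
#' compute_statistics(X, c(0, 0, 0, 1, 1, 1), test = "t")$teststat
#' @export
compute_statistics <- function(X, classlabel, test = "t", side = "abs",
                               nonpara = "n", na = NA) {
  test <- match.arg(test, names(.TEST_CODES))
  side <- match.arg(side, names(.SIDE_CODES))
  structure <- test_structure(test)
  X <- .prepare_matrix(X, na)
  labels <- validate_labels(classlabel, structure)
  if (length(labels) != ncol(X))
    stop("classlabel length must equal the number of samples (columns)")
  if (test == "wilcoxon" || identical(nonpara, "y")) X <- .rank_rows(X)
  k <- .design_k(labels, structure)
  s <- stat_vector_cpp(t(X), labels, .TEST_CODES[[test]], k)
  list(teststat = s,
       extreme = .side_transform(s, side),
       defined = !is.na(s))
}

# thin single-gene wrappers over the same compiled path ----------------

.single_row_stat <- function(values, labels, test) {
  X <- matrix(as.numeric(values), nrow = 1L)
  compute_statistics(X, labels, test = test, side = "upper")$teststat[1L]
}

#' Two-sample Welch t statistic (unequal variances)
#'
#' @param group0,group1 Numeric vectors with at least 2 values each.
#' @return The statistic, or `NA` if undefined (zero denominator or too
#'   few values).
#' @export
welch_t <- function(group0, group1) {
  .single_row_stat(c(group0, group1),
                   rep(c(0L, 1L), c(length(group0), length(group1))), "t")
}

#' Two-sample pooled-variance t statistic
#' @inheritParams welch_t
#' @return The statistic, or `NA` if undefined.
#' @export
t_equalvar <- function(group0, group1) {
  .single_row_stat(c(group0, group1),
                   rep(c(0L, 1L), c(length(group0), length(group1))),
                   "t.equalvar")
}

#' Standardized Wilcoxon rank-sum statistic
#'
#' Midranks over the pooled values; `z = (W - n0(n+1)/2) /
#' sqrt(n0 n1 (n+1)/12)` where `W` is the rank sum of `group0`.  No tie
#' correction is applied to the variance term.
#'
#' @param group0,group1 Numeric vectors with at least 1 value each.
#' @return The statistic, or `NA` if undefined.
#' @export
wilcoxon_std <- function(group0, group1) {
  .single_row_stat(c(group0, group1),
                   rep(c(0L, 1L), c(length(group0), length(group1))),
                   "wilcoxon")
}

#' One-way ANOVA F statistic
#'
#' @param groups List of numeric vectors, one per group.
#' @return `F = (SSB/(k-1)) / (SSW/(n-k))`, or `NA` if undefined.
#' @export
anova_f <- function(groups) {
  .single_row_stat(unlist(groups),
                   rep(seq_along(groups) - 1L, lengths(groups)), "f")
}

#' Paired t statistic
#'
#' @param pairs Two-column numeric matrix (treated, control), one row
#'   per pair.
#' @return `dbar / (s_d / sqrt(npairs))` over complete pairs, or `NA`.
#' @export
paired_t <- function(pairs) {
  pairs <- as.matrix(pairs)
  values <- as.vector(t(pairs))               # treated, control, ...
  .single_row_stat(values, rep(c(1L, 0L), nrow(pairs)), "pairt")
}

#' Randomized-block F statistic
#'
#' Two-way ANOVA without replication on a blocks x treatments table:
#' `F = (SStreat/(k-1)) / (SSresid/((k-1)(b-1)))` with
#' `SSresid = SStot - SSblock - SStreat`.
#'
#' @param blocks Numeric matrix, one row per block, one column per
#'   treatment.
#' @return The statistic, or `NA` if undefined.
#' @export
block_f <- function(blocks) {
  blocks <- as.matrix(blocks)
  k <- ncol(blocks)
  .single_row_stat(as.vector(t(blocks)), rep(0:(k - 1L), nrow(blocks)),
                   "blockf")
}
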