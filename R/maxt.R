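# Step-down maxT engine: gene ordering, successive maxima, chunk
# accumulation (compiled), reduction and finalization.
#
# Counts of "permuted statistic at least as extreme as observed" are
# exact integers, so reducing per-chunk accumulators is order
# independent and a chunked run reproduces a serial run bit for bit.

# comparison tolerance: identical algebraic statistics can differ in the
# last bits between labellings; the tolerance guarantees the identity
# labelling always counts, hence p >= 1/B.
.MAXT_EPS <- 1e-10

#' Order genes by decreasing observed extremeness
#'
#' Defined genes are sorted by decreasing side-transformed statistic,
#' ties broken by ascending input index; genes whose observed statistic
#' is undefined are appended in input order and excluded from the
#' step-down walk.
#'
#' @param extreme Numeric vector of side-transformed observed
#'   statistics, `NA` where undefined.
#' @return List with `order` (permutation of gene indices) and
#'   `defined_count`.
#' @export
order_genes <- function(extreme) {
  if (all(is.na(extreme)))
    stop("all observed statistics are undefined; nothing to test")
  list(order = order(-extreme, na.last = TRUE),
       defined_count = sum(!is.na(extreme)))
}

#' Successive maxima of a permuted statistic vector
#'
#' The maxT null distribution at rank i is the maximum of the permuted
#' statistics of the genes at ranks i..defined_count (least to most
#' significant).  Undefined permuted statistics enter as `-Inf`.
#'
#' @param extreme Numeric vector of side-transformed permuted
#'   statistics in original gene order (`NA` = undefined).
#' @param ordering Result of [order_genes()] on the observed statistics.
#' @return Numeric vector in rank order; positions beyond
#'   `defined_count` are `NA`.
#' @export
successive_maxima <- function(extreme, ordering) {
  d <- ordering$defined_count
  u <- rep(NA_real_, length(extreme))
  e <- extreme[ordering$order[seq_len(d)]]
  e[is.na(e)] <- -Inf
  u[seq_len(d)] <- rev(cummax(rev(e)))
  u
}

# internal: everything the kernel needs, computed once per run
.prep_engine <- function(X, classlabel, test, side, nonpara, na) {
  test <- match.arg(test, names(.TEST_CODES))
  side <- match.arg(side, names(.SIDE_CODES))
  structure <- test_structure(test)
  X <- .prepare_matrix(X, na)
  labels <- validate_labels(classlabel, structure)
  if (length(labels) != ncol(X))
    stop("classlabel length must equal the number of samples (columns)")
  if (test == "wilcoxon" || identical(nonpara, "y")) X <- .rank_rows(X)
  k <- .design_k(labels, structure)
  teststat <- stat_vector_cpp(t(X), labels, .TEST_CODES[[test]], k)
  extreme <- .side_transform(teststat, side)
  ordering <- order_genes(extreme)
  list(Xt = t(X), labels = labels, structure = structure,
       test = test, side = side, k = k,
       test_code = .TEST_CODES[[test]], side_code = .SIDE_CODES[[side]],
       teststat = teststat, obs_ext = extreme, ordering = ordering,
       gene_ids = if (is.null(rownames(X))) as.character(seq_len(nrow(X)))
                  else rownames(X))
}

# internal fast path used by workers
.kernel_chunk <- function(prep, chunk_labels) {
  maxt_kernel_cpp(prep$Xt, chunk_labels, prep$test_code, prep$k,
                  prep$side_code, prep$ordering$order - 1L,
                  prep$ordering$defined_count, prep$obs_ext, .MAXT_EPS)
}

#' Accumulate extremeness counts over a chunk of labellings
#'
#' For each labelling in the chunk, the per-gene raw count is
#' incremented when the permuted statistic is at least as extreme as the
#' observed one (within tolerance), and the per-rank count when the
#' successive maximum at that rank is.  `processed` tracks the chunk
#' length.
#'
#' @param X Genes x samples matrix (`NA` = missing).
#' @param chunk Integer matrix of labellings, one column each (e.g. from
#'   [complete_stream()] or [random_stream()]).
#' @param classlabel The observed labelling; it defines the observed
#'   statistics and the gene ordering against which the chunk is
#'   counted.
#' @param test,side,nonpara,na As in [compute_statistics()].
#' @param acc Optional accumulator from a previous call to add onto.
#' @return List with `raw_counts`, `adj_counts` (indexed by rank
#'   position) and `processed`.
#' @export
accumulate_chunk <- function(X, chunk, classlabel, test = "t", side = "abs",
                             nonpara = "n", na = NA, acc = NULL) {
  prep <- .prep_engine(X, classlabel, test, side, nonpara, na)
  part <- .kernel_chunk(prep, chunk)
  if (is.null(acc)) part else reduce_accumulators(list(acc, part))
}

#' Sum per-chunk accumulators
#'
#' Element-wise integer sums; order of the parts is irrelevant.
#'
#' @param parts List of accumulators from [accumulate_chunk()] /
#'   worker kernels.
#' @return A single accumulator.
#' @export
reduce_accumulators <- function(parts) {
  Reduce(function(a, b) list(raw_counts = a$raw_counts + b$raw_counts,
                             adj_counts = a$adj_counts + b$adj_counts,
                             processed = a$processed + b$processed),
         parts)
}

#' Raw and step-down adjusted p-values from an accumulator
#'
#' `rawp = raw_count / B`; adjusted p-values are the per-rank
#' proportions with monotonicity enforced along the rank order
#' (`adjp[i] = max(adjp[i-1], adjp[i])`).  Genes with an undefined
#' observed statistic get `NA` p-values and sort to the tail.
#'
#' @param acc Accumulator with `processed` equal to the total
#'   permutation count `B` (identity included).
#' @param ordering Result of [order_genes()].
#' @param teststat Signed observed statistics (reported as-is).
#' @param gene_ids Character gene identifiers.
#' @return A `data.frame` of class `maxt_result`, rows in rank order,
#'   with columns `gene_id`, `index` (rank, 1-based), `teststat`,
#'   `rawp`, `adjp`, and attribute `B`.
#' @export
finalize_pvalues <- function(acc, ordering, teststat, gene_ids = NULL) {
  B <- acc$processed
  if (is.null(B) || B < 1) stop("no permutations processed")
  m <- length(acc$raw_counts)
  d <- ordering$defined_count
  ord <- ordering$order
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(m))
  rawp <- acc$raw_counts[ord] / B
  adjp <- rep(NA_real_, m)
  adjp[seq_len(d)] <- cummax(acc$adj_counts[seq_len(d)] / B)
  if (d < m) rawp[(d + 1L):m] <- NA_real_
  out <- data.frame(gene_id = gene_ids[ord],
                    index = seq_len(m),
                    teststat = teststat[ord],
                    rawp = rawp,
                    adjp = adjp,
                    stringsAsFactors = FALSE)
  attr(out, "B") <- B
  class(out) <- c("maxt_result", "data.frame")
  out
}
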