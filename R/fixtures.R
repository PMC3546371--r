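# Synthetic datasets with known structure, and an independent
# brute-force implementation of the full maxT procedure used as the
# oracle throughout the test suite.  The oracle shares nothing with the
# compiled engine: it enumerates labellings its own way (combn /
# expand.grid / recursion), evaluates textbook formulas through base R,
# and counts by explicit double loops.

#' Generate a synthetic expression dataset
#'
#' Gene-independent Gaussian noise with unit within-group variance; the
#' first `n_signal` genes carry a mean shift of `delta` (in within-group
#' SD units) in the treated arm (label 1).  For paired and blocked
#' designs a per-gene, per-pair/block additive offset of SD `block_sd`
#' induces the within-block correlation those statistics remove.
#' Missing cells are introduced completely at random at rate
#' `missing_rate` (any row left fully missing gets one value restored).
#'
#' @param m Number of genes.
#' @param structure `"two_group"`, `"k_group"`, `"paired"` or
#'   `"blocked"`.
#' @param design Group sizes for the group structures (e.g.
#'   `c(38, 38)`), the number of pairs for `"paired"`, or
#'   `c(nblocks, k)` for `"blocked"`.
#' @param n_signal Number of signal genes (first rows).
#' @param delta Mean shift of signal genes, in within-group SD units.
#' @param block_sd SD of the additive pair/block offsets.
#' @param missing_rate Probability a cell is missing, in `[0, 0.5]`.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return List with `X` (matrix, `NA` for missing, rownames
#'   `gene_00001`, ...), `classlabel`, `truth` (logical signal mask)
#'   and `structure`.
#' @export
generate_dataset <- function(m = 6102, structure = "two_group",
                             design = c(38, 38), n_signal = 0,
                             delta = 1, block_sd = 1, missing_rate = 0,
                             seed = 1) {
  structure <- match.arg(structure, .STRUCTURES)
  if (n_signal > m) stop("n_signal must not exceed m")
  if (missing_rate < 0 || missing_rate > 0.5)
    stop("missing_rate must be in [0, 0.5]")
  set.seed(seed)
  classlabel <- switch(structure,
    two_group = rep(c(0L, 1L), design),
    k_group = rep(seq_along(design) - 1L, design),
    paired = rep(c(0L, 1L), design),
    blocked = rep(0:(design[2L] - 1L), design[1L]))
  n <- length(classlabel)
  X <- matrix(rnorm(m * n), m, n)
  if (structure %in% c("paired", "blocked")) {
    k <- if (structure == "paired") 2L else design[2L]
    nb <- n %/% k
    offsets <- matrix(rnorm(m * nb, sd = block_sd), m, nb)
    X <- X + offsets[, rep(seq_len(nb), each = k), drop = FALSE]
  }
  truth <- seq_len(m) <= n_signal
  if (n_signal > 0)
    X[truth, classlabel == 1L] <- X[truth, classlabel == 1L] + delta
  if (missing_rate > 0) {
    drop <- matrix(runif(m * n) < missing_rate, m, n)
    full <- which(rowSums(!drop) == 0L)
    for (g in full) drop[g, sample.int(n, 1L)] <- FALSE
    X[drop] <- NA_real_
  }
  rownames(X) <- sprintf("gene_%05d", seq_len(m))
  list(X = X, classlabel = classlabel, truth = truth,
       structure = structure)
}

# ---- independent enumeration of admissible labellings ---------------

.bf_enumerate <- function(labels, structure) {
  n <- length(labels)
  switch(structure,
    two_group = {
      pos <- utils::combn(n, sum(labels == 0L))
      apply(pos, 2L, function(p) {
        l <- rep(1L, n); l[p] <- 0L; l
      })
    },
    k_group = {
      rec <- function(counts) {
        if (sum(counts) == 0L) return(list(integer(0)))
        out <- list()
        for (v in which(counts > 0L)) {
          c2 <- counts; c2[v] <- c2[v] - 1L
          out <- c(out, lapply(rec(c2), function(tail) c(v - 1L, tail)))
        }
        out
      }
      do.call(cbind, rec(tabulate(labels + 1L)))
    },
    paired = {
      np <- n %/% 2L
      bits <- as.matrix(expand.grid(rep(list(0:1), np)))
      apply(bits, 1L, function(b) as.integer(rbind(b, 1L - b)))
    },
    blocked = {
      k <- max(labels) + 1L
      nb <- n %/% k
      perms <- function(v) {
        if (length(v) <= 1L) return(list(v))
        out <- list()
        for (i in seq_along(v))
          out <- c(out, lapply(perms(v[-i]), function(tail) c(v[i], tail)))
        out
      }
      pk <- perms(0:(k - 1L))
      choice <- as.matrix(expand.grid(rep(list(seq_along(pk)), nb)))
      apply(choice, 1L, function(ch)
        as.integer(unlist(pk[ch])))
    })
}

# textbook statistic formulas through base R (independent of the
# compiled kernel)
.bf_stat <- function(x, lab, test) {
  ok <- !is.na(x)
  switch(test,
    t = {
      a <- x[ok & lab == 0L]; b <- x[ok & lab == 1L]
      if (length(a) < 2L || length(b) < 2L) return(NA_real_)
      den <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
      if (!is.finite(den) || den <= 0) return(NA_real_)
      (mean(a) - mean(b)) / den
    },
    t.equalvar = {
      a <- x[ok & lab == 0L]; b <- x[ok & lab == 1L]
      na_ <- length(a); nb_ <- length(b)
      if (na_ < 2L || nb_ < 2L) return(NA_real_)
      sp2 <- ((na_ - 1) * stats::var(a) + (nb_ - 1) * stats::var(b)) /
        (na_ + nb_ - 2)
      den <- sqrt(sp2 * (1 / na_ + 1 / nb_))
      if (!is.finite(den) || den <= 0) return(NA_real_)
      (mean(a) - mean(b)) / den
    },
    wilcoxon = {
      # x already holds midranks
      n0 <- sum(ok & lab == 0L); n1 <- sum(ok & lab == 1L)
      if (n0 == 0L || n1 == 0L) return(NA_real_)
      nn <- n0 + n1
      W <- sum(x[ok & lab == 0L])
      (W - n0 * (nn + 1) / 2) / sqrt(n0 * n1 * (nn + 1) / 12)
    },
    f = {
      y <- x[ok]; g <- factor(lab[ok])
      if (nlevels(droplevels(g)) < 2L) return(NA_real_)
      g <- droplevels(g)
      if (length(y) <= nlevels(g)) return(NA_real_)
      ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
      ssb <- sum(tapply(y, g, length) *
                   (tapply(y, g, mean) - mean(y))^2)
      if (ssw <= 0) return(NA_real_)
      (ssb / (nlevels(g) - 1)) / (ssw / (length(y) - nlevels(g)))
    },
    pairt = {
      np <- length(x) %/% 2L
      d <- vapply(seq_len(np), function(p) {
        i <- 2L * p - 1L; j <- 2L * p
        if (is.na(x[i]) || is.na(x[j])) return(NA_real_)
        if (lab[i] == 1L) x[i] - x[j] else x[j] - x[i]
      }, numeric(1))
      d <- d[!is.na(d)]
      if (length(d) < 2L || stats::sd(d) <= 0) return(NA_real_)
      mean(d) / (stats::sd(d) / sqrt(length(d)))
    },
    blockf = {
      k <- max(lab) + 1L
      nb <- length(x) %/% k
      tab <- matrix(NA_real_, nb, k)
      for (j in seq_len(nb)) {
        idx <- (j - 1L) * k + seq_len(k)
        if (anyNA(x[idx])) next
        tab[j, lab[idx] + 1L] <- x[idx]
      }
      tab <- tab[stats::complete.cases(tab), , drop = FALSE]
      b <- nrow(tab)
      if (b < 2L) return(NA_real_)
      grand <- mean(tab)
      sstr <- b * sum((colMeans(tab) - grand)^2)
      ssblock <- k * sum((rowMeans(tab) - grand)^2)
      sstot <- sum((tab - grand)^2)
      ssres <- sstot - ssblock - sstr
      if (ssres <= 0) return(NA_real_)
      (sstr / (k - 1)) / (ssres / ((k - 1) * (b - 1)))
    })
}

#' Brute-force maxT oracle (complete enumeration, toy scale)
#'
#' Explicitly materializes the full permutations x genes statistic
#' matrix and obtains raw and step-down adjusted p-values by direct
#' double loops over the definition of the procedure.  Enumeration,
#' statistic formulas and counting are all independent of the compiled
#' engine; results must nevertheless agree exactly.
#'
#' @inheritParams compute_statistics
#' @return A `data.frame` shaped like the output of [pmaxt()].
#' @export
brute_force_maxt <- function(X, classlabel, test = "t", side = "abs",
                             nonpara = "n", na = NA) {
  structure <- test_structure(test)
  X <- .prepare_matrix(X, na)
  labels <- validate_labels(classlabel, structure)
  N <- count_complete(labels, structure)
  if (N > 10000) stop("brute-force oracle is restricted to enumerations <= 10000")
  if (test == "wilcoxon" || identical(nonpara, "y"))
    X <- .rank_rows(X)
  all_labs <- .bf_enumerate(labels, structure)     # n x N
  m <- nrow(X)
  side_fun <- switch(side, abs = abs, upper = identity,
                     lower = function(s) -s)
  S <- matrix(NA_real_, N, m)
  for (p in seq_len(N))
    for (g in seq_len(m))
      S[p, g] <- .bf_stat(X[g, ], all_labs[, p], test)
  E <- side_fun(S)
  E[is.na(E)] <- -Inf
  obs_stat <- vapply(seq_len(m), function(g)
    .bf_stat(X[g, ], labels, test), numeric(1))
  obs_ext <- side_fun(obs_stat)
  ord <- order(-obs_ext, na.last = TRUE)
  d <- sum(!is.na(obs_ext))
  eps <- .MAXT_EPS
  raw <- integer(m); adj <- integer(m)
  for (p in seq_len(N)) {
    for (g in seq_len(m))
      if (!is.na(obs_ext[g]) && E[p, g] >= obs_ext[g] - eps)
        raw[g] <- raw[g] + 1L
    u <- -Inf
    for (r in d:1) {
      g <- ord[r]
      if (E[p, g] > u) u <- E[p, g]
      if (u >= obs_ext[g] - eps) adj[r] <- adj[r] + 1L
    }
  }
  rawp <- raw[ord] / N
  adjp <- rep(NA_real_, m)
  adjp[seq_len(d)] <- cummax(adj[seq_len(d)] / N)
  if (d < m) rawp[(d + 1L):m] <- NA_real_
  ids <- if (is.null(rownames(X))) as.character(seq_len(m)) else rownames(X)
  out <- data.frame(gene_id = ids[ord], index = seq_len(m),
                    teststat = obs_stat[ord], rawp = rawp, adjp = adjp,
                    stringsAsFactors = FALSE)
  attr(out, "B") <- N
  out
}
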