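# maxtperm

Family-wise error rate (FWER) control for gene-by-gene permutation
tests on expression matrices, via the step-down **maxT** procedure of
Westfall and Young, with a chunked parallel executor whose results are
**bit-identical to a serial run for any worker count**.

## Who this is for

Biostatisticians running `mt.maxT`-style differential-expression
analyses who are limited by the elapsed time of the permutation count
rather than by memory: the interface of `pmaxt()` mirrors
`multtest::mt.maxT` (`test`, `side`, `fixed.seed.sampling`, `B`, `na`,
`nonpara`, same defaults), and extra arguments (`processes`,
`backend`, `seed`) distribute the permutations across workers without
changing a single digit of the answer.

## The method

For an `m x n` matrix and per-sample class labels, `B` label
permutations are drawn (permutation 0 is the observed labelling,
processed exactly once) and the chosen statistic is recomputed for
every gene under every relabelling. With genes ordered by decreasing
observed extremeness |t|(1) ≥ |t|(2) ≥ …:

* raw p-value: `rawp_j = #{b : |t_j^(b)| ≥ |t_j|} / B`
* adjusted p-value at rank i: the permutation frequency of
  `u_i^(b) = max_{r ≥ i} |t_(r)^(b)|` exceeding `|t_(i)|`, followed by
  monotonicity enforcement `adjp_(i) = max(adjp_(i-1), adjp_(i))`.

This controls the FWER while borrowing the genes' joint correlation
structure from the data. Six statistics are supported: Welch t
(`t`), pooled-variance t (`t.equalvar`), standardized Wilcoxon rank
sum (`wilcoxon`), one-way F (`f`), paired t (`pairt`) and
randomized-block F (`blockf`). Missing values (the `na` code) are
excluded per gene; `nonpara = "y"` midrank-transforms each gene first.

Two permutation generators are provided: complete lexicographic
enumeration (`B = 0`; refused above `complete.cap` with a request for
a smaller explicit `B`) and counter-based Monte Carlo sampling, both
supporting O(1) forwarding to any stream index so the permutation
count can be split into equal chunks across workers and the reduced
counts reproduce the serial result exactly.

## Worked example

```r
library(maxtperm)
set.seed(1)
X <- matrix(rnorm(20 * 8), 20, dimnames = list(sprintf("g%02d", 1:20)))
X[1, 5:8] <- X[1, 5:8] + 3          # one strongly shifted gene
lab <- rep(c(0L, 1L), each = 4)
res <- pmaxt(X, lab, B = 0)         # complete enumeration: choose(8,4) = 70
head(res, 4)
#>   gene_id index teststat    rawp   adjp
#> 1     g11     1    2.844 0.05714 0.4571
#> 2     g19     2    2.789 0.05714 0.4571
#> 3     g01     3   -1.946 0.08571 0.8000
#> 4     g07     4   -1.770 0.11429 0.8286
```

Rows are ordered by decreasing |t| (`index` is the rank); `teststat`
is the signed Welch statistic (group 0 minus group 1, so the shifted
gene g01 is negative); `rawp` is the fraction of the 70 complete
relabelings at least as extreme as the observed one (the two-sided
floor here is 2/70 ≈ 0.029, since a split and its complement share
|t|), and `adjp` is the step-down maxT adjustment across all 20 genes
— with only 70 permutations and 20 genes, no gene can reach adjusted
significance, which is exactly why one scales `B` up on real data,
e.g.:

```r
res <- pmaxt(X, lab, B = 200000, processes = 8, seed = 7)
```

A command-line front end (`exec/pmaxt`) and a synthetic-data generator
(`exec/pmaxt-simulate`) wrap the same functions; see
`vignettes/maxt-permutation-testing.Rmd` for the model, the generator
design and the numerical choices.

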