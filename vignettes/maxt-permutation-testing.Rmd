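---
title: "Permutation maxT testing: model, generators and parallel contract"
author: "maxtperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation maxT testing: model, generators and parallel contract}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxtperm)
```

## The problem and the procedure

Gene-by-gene differential-expression testing on an `m x n` expression
matrix produces `m` p-values, and controlling the probability of even
one false rejection (the family-wise error rate, FWER) across thousands
of genes requires a multiplicity adjustment that respects the joint
distribution of the statistics. The step-down maxT procedure of
Westfall and Young does this by resampling: the class labels of the
columns are permuted `B` times (the identity labelling is permutation
0, processed exactly once), the chosen statistic is recomputed for
every gene under every relabelling, and

* the **raw p-value** of gene *j* is the fraction of the `B`
  labellings (identity included) whose statistic is at least as
  extreme as the observed one;
* the **adjusted p-value** at rank *i* (genes ordered by decreasing
  observed extremeness) is the fraction of labellings in which the
  *successive maximum* — the max of the permuted statistics over ranks
  `i..m` — is at least as extreme as the observed statistic at rank
  *i*, followed by a monotonicity pass
  `adjp[i] = max(adjp[i-1], adjp[i])`.

Because the null distribution is taken from the data's own
permutations, the procedure is valid under the sole assumption that
labels are exchangeable under the null, and it inherits the
correlation structure between genes, which is what makes maxT less
conservative than Bonferroni on correlated expression data.

`pmaxt()` mirrors the `mt.maxT` interface of the multtest package:
`test`, `side`, `fixed.seed.sampling`, `B`, `na` and `nonpara` have
the same names and defaults (`t`, `abs`, `y`, `10000`, `n`).

## The six statistics

All statistics are computed per gene on its non-missing values only —
a missing value behaves exactly like a deleted sample for that gene —
and all use `n - 1` sample-variance denominators.

| `test` | statistic | label structure |
|---|---|---|
| `t` | Welch t, `(x̄0 − x̄1)/√(s0²/n0 + s1²/n1)` | labels 0/1 |
| `t.equalvar` | pooled-variance t | labels 0/1 |
| `wilcoxon` | standardized rank sum `z = (W − n0(n+1)/2)/√(n0 n1 (n+1)/12)` | labels 0/1 |
| `f` | one-way `F = (SSB/(k−1))/(SSW/(n−k))` | labels 0..k−1 |
| `pairt` | `d̄/(s_d/√npairs)` over complete pairs | consecutive pairs, one 0 and one 1 each |
| `blockf` | `F = (SStr/(k−1))/(SSres/((k−1)(b−1)))`, `SSres = SStot − SSblock − SStr` | consecutive blocks, each treatment once |

Design choices worth stating explicitly:

* **Wilcoxon ties** are handled by midranks with *no* tie correction
  in the variance term; this keeps the statistic the simple
  standardized rank sum and is a deliberate, testable choice.
* **`nonpara = "y"`** replaces each gene's non-missing values by their
  midranks before the chosen statistic is computed. Ranks depend only
  on the gene's values, never on the labelling, so the transform is
  applied once per gene up front.
* **Undefined statistics** (zero denominators; fewer than 2
  non-missing values per group for the t family; fewer than 2
  represented groups for `f`; fewer than 2 complete pairs/blocks) are
  flagged, never fatal. A gene undefined on the *observed* labelling
  is excluded from the ranking and reported with `NA` p-values; a
  statistic undefined under a *permuted* labelling enters the counts
  as `-Inf`, i.e. never extreme. This keeps every count well defined.
* **`side`** folds the statistic so that larger always means more
  extreme (`abs` → |s|, `upper` → s, `lower` → −s); the reported
  `teststat` column stays signed.
* The per-gene kernel is compiled (Rcpp), as in the C implementations
  this procedure descends from; one code path serves the observed and
  every permuted labelling, so the identity permutation is compared
  against itself by construction.

## Permutation generators

Four assignment spaces are enumerated or sampled, depending on the
test: two-group splits (`choose(n, n1)` assignments), multiset label
permutations (`n!/(n1!…nk!)`), within-pair swaps (`2^npairs`) and
within-block rearrangements (`(k!)^nblocks`).

**Complete enumeration** (`B = 0`) walks the canonical lexicographic
order via rank/unrank bijections (combination and Lehmer unranking),
with the observed labelling's own slot omitted so that the stream
`[observed, enumeration minus observed]` contains every admissible
assignment exactly once. Unranking makes forwarding to any stream
index O(index-free): a worker asked for elements `skip..skip+count−1`
computes them directly. Enumerations larger than `complete.cap`
(default `1e7`, user-overridable) are refused with a request to choose
a smaller explicit `B`; the cap also keeps all enumeration arithmetic
exact in doubles.

**Random (Monte Carlo) mode** (`B > 0`) samples assignments uniformly
*with replacement*. Element `i ≥ 1` of the stream is produced by a
counter-based generator: a MurmurHash3-finalizer hash keyed on
`(seed, i, draw)` yields the uniforms, and the permuted labels are
`labels[order(u)]` (order statistics of i.i.d. uniforms give a uniform
random permutation; per-pair bits and per-block orderings handle the
paired and blocked spaces). Because element `i` is a pure function of
`(seed, i, observed)`, any partition of `1..B-1` into chunks
reproduces the serial stream exactly — the load-bearing property
behind splitting the permutation count across workers. It also makes
`fixed.seed.sampling = "y"` (generate on the fly) and `"n"`
(materialize the stream in memory first) produce bit-identical
results; the option only trades memory against recomputation.

## The parallel contract

The executor follows a six-step master/worker pattern: validate and
transform parameters; distribute the plan; build the derived data
(rank transform, transposed matrix, observed statistics, gene
ordering) once; run the counting kernel over per-worker chunks;
gather; finalize p-values on the master. The `B − 1` non-identity
indices are split into `P` contiguous chunks whose sizes differ by at
most one (earlier workers take the remainder); the master additionally
owns index 0, so the identity labelling is processed exactly once.

What each worker returns are *integer counts* (exact integers carried
in doubles), and integer addition is associative and commutative, so
the gathered reduction is independent of worker count, scheduling and
backend — `pmaxt(..., processes = P)` is bit-identical to
`run_serial_reference(...)` for every `P`. Three backends share this
contract: `serial`, `process_pool` (forked workers) and
`message_passing` (a socket cluster with explicit broadcast and
gather). Each run records elapsed seconds for the five profiled
stages (pre-processing, parameter distribution, data setup, main
kernel, p-value computation), so users can reproduce the scaling
shape of the kernel on their own hardware; absolute timings are of
course machine-dependent, and on a single-core host forked workers
cannot beat the serial kernel.

Whether the master should own only the identity or also an equal share
of the `B − 1` permutations is genuinely open; here the master takes an
equal chunk plus the identity, which keeps all `P` workers busy and the
chunk arithmetic uniform.

## Numerical choices

* **Extremeness tolerance.** Counts use `permuted ≥ observed − 1e-10`
  (absolute). Algebraically identical statistics can differ in the
  last bits between labellings; the tolerance guarantees in particular
  that the identity labelling always counts, so every defined p-value
  is at least `1/B`. The brute-force oracle applies the same rule, as
  part of the procedure's definition.
* **Ties in the gene ordering** are broken by ascending input index
  (a stable sort), and genes with undefined observed statistics occupy
  the tail in input order.
* **`B = 1`** (identity only) is legal and yields p-values of 1 for
  every defined gene.
* `blockf` declares the statistic undefined when
  `SSres = SStot − SSblock − SStr ≤ 0`; data constant within each
  block land here (all variation is block variation), as do tiny
  negative residuals from cancellation.

## The synthetic generator and what the tests show

`generate_dataset()` emulates a preprocessed expression study shaped
like a 6102-gene, 76-sample (38 vs 38) microarray: gene-independent
Gaussian noise with unit within-group variance, a mean shift of
`delta` within-group SDs in the treated arm for the first `n_signal`
genes, additive per-gene pair/block offsets (SD `block_sd`) for the
paired and blocked designs, and completely-at-random missingness.
What it deliberately does *not* model: inter-gene correlation,
intensity-dependent variance, probe effects or heavy-tailed noise.
Calibration results on it (uniform raw p-values under the null, FWER
of the min-adjp rule within binomial error of its nominal level)
therefore certify the *procedure*, not robustness to real microarray
artefacts — though the permutation construction itself is
distribution-free given exchangeability.

Problem sizes used by the test-suite checks are chosen at toy-to-small
scale so each contract is exercised exhaustively rather than
approximately: complete enumerations of 32–1000 labellings against a
brute-force double-loop oracle; worker-count invariance at 200 genes ×
20 samples × 1000 permutations; calibration at 2000 null genes (70
complete permutations) and 500 replicate datasets; uniformity at
70 000 draws over 70 assignments; and a scaling-shape timing on a
6102 × 76 matrix at 1500 permutations.

## Worked example

```{r}
set.seed(1)
X <- matrix(rnorm(20 * 8), 20, dimnames = list(sprintf("g%02d", 1:20)))
X[1, 5:8] <- X[1, 5:8] + 3          # one strongly shifted gene
lab <- rep(c(0L, 1L), each = 4)
res <- pmaxt(X, lab, B = 0)         # complete enumeration: 70 labellings
head(res, 4)
```

With only `choose(8, 4) = 70` admissible relabelings the smallest
achievable two-sided raw p-value is `2/70 ≈ 0.029`, and the step-down
adjustment across 20 genes lifts the shifted gene's adjusted p-value
accordingly — tiny designs simply cannot certify strong significance,
which is exactly why one scales `B` up on real data.

## Known limitations

* Only the four permutation structures above; no stratified or
  restricted permutation schemes, and no antithetic/balanced sampling.
* Random mode samples with replacement, as standard Monte Carlo.
* minP adjustment, FDR procedures and moderated-variance statistics
  are out of scope.
* The keyed random stream is reproducible given `(seed, B)` chunking —
  but it is this package's stream; it does not reproduce the bit
  stream of other implementations (nor do they reproduce each other's).
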