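Package: maxtperm
Title: Parallel Westfall-Young maxT Permutation Adjusted p-Values
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Step-down maxT adjusted p-values of Westfall and Young for
    gene-by-gene permutation tests on expression matrices, mirroring the
    mt.maxT interface of the multtest package. Supports six test
    statistics (Welch t, pooled-variance t, standardized Wilcoxon rank
    sum, one-way F, paired t and randomized-block F), random (Monte
    Carlo) and complete-enumeration permutation generators with O(1)
    forwarding, and a chunked parallel executor whose results are
    bit-identical to a serial run for any worker count.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
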