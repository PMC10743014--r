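Package: promhap
Title: Promoter Haplotype Analysis for Case-Control SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Haplotype-level analysis of promoter SNP panels in two-group
    (case-control) cohorts: expectation-maximization haplotype phasing from
    unphased diploid genotypes, Hardy-Weinberg exact tests, pairwise linkage
    disequilibrium (D, D', r, r2) with Fisher and chi-square significance,
    exact and Monte-Carlo group differentiation tests, AMOVA-style Fst and
    distance-based PhiST with permutation p-values, median-joining haplotype
    networks with reticulation detection, a cumulative mutation-burden
    statistic compared between groups, and per-haplotype transcription-factor
    binding-site scoring from JASPAR position frequency matrices. Includes a
    seeded synthetic-cohort generator with bundled ATG16L1 and ATG5 promoter
    panels whose haplotype frequencies emulate a sporadic Parkinson's disease
    case-control study, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    vcfR,
    Biostrings,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
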