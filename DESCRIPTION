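Package: dmrkit
Title: Differential Methylation Region Calling and Multi-Omic Integration for Cohort WGBS Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for smoker-versus-nonsmoker (or any two-group)
    whole-genome bisulfite sequencing cohorts: per-CpG methylation levels with
    common-SNP filtering, depth-weighted local smoothing, covariate- and
    cell-composition-adjusted per-site association, candidate-region merging with
    an autocorrelation-corrected Stouffer-Liptak-Kechris combined p-value,
    matched-region permutation enrichment against annotation tracks, count-based
    differential expression with mean-variance precision weights, regulatory
    (promoter/enhancer) DMR-to-gene Spearman integration with direction-quadrant
    classification, and covariate-adjusted cytokine panel testing. A
    seed-reproducible synthetic cohort generator with a ground-truth ledger makes
    every stage testable without access to protected human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
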