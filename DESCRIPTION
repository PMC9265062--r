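Package: avpcm
Title: Multi-Assay Classification and Concordance Analysis for the
    Aggressive Variant Prostate Cancer Molecular Profile
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies TP53, RB1 and PTEN tumor-suppressor status from
    immunohistochemistry intensity reads, targeted-sequencing variant and
    copy-number tables, and loss-of-function transcriptional signature
    scores, and quantifies inter-reader and cross-assay agreement.
    Implements labeling-index scoring with configurable intensity schemes
    and 10% cutoffs, nine-read consensus calling, Fleiss' kappa for
    multi-reader agreement, rule-based variant pathogenicity (CADD bins
    and consequence fallback) and copy-number deletion calls, cohort-relative
    signature scoring with >0 dichotomization, Cohen's kappa with
    asymptotic 95% confidence intervals, method-combination (union) calls,
    and the composite two-of-three AVPC-m determination. A seeded synthetic
    cohort generator emulates the 28-sample, 3-lab x 3-reader study design
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
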