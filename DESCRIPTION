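Package: azasig
Title: Response Signatures and Clonal Dynamics for Azacytidine-Treated MDS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for paired pre-/post-azacytidine (AZA)
    myelodysplastic syndrome (MDS) cohorts: variant-allele-frequency (VAF)
    filtering with paired rescue rules and clonal dynamics classification,
    transition/transversion spectrum summaries, lightweight differential
    expression with median-of-ratios normalization, derivation of
    responder/non-responder gene signatures, a delta(NR-R) median-split
    transcriptional classifier with high/low stratification, and
    Kaplan-Meier/log-rank survival evaluation. Includes seeded synthetic
    cohort generators (negative-binomial counts, paired variant tables,
    survival cohorts with a planted expression-dependent hazard) so every
    stage is testable by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
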