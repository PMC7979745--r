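Package: crescreen
Title: Tiling CRISPRi Screen Analysis for Risk Cis-Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pooled CRISPR-interference tiling screens of
    cis-regulatory elements harboring disease-risk SNPs: tiling sgRNA
    library design with equidistant declustering, guide counting and
    median-ratio normalization, negative-binomial guide depletion tests,
    100-bp sliding-window robust rank aggregation with permutation
    p-values, cross-cell-line differential essentiality (studentized
    residual outlier test, empirical Brown's combination, locus
    enrichment), association of depletion scores with epigenomic signal
    and SNP odds ratios, PWM motif scanning, and methylation-stratified
    eQTL regression. Includes seeded synthetic-data generators with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    DESeq2,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
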