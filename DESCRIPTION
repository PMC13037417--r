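Package: mirvalid
Title: miRNA Biomarker Validation: Differential Expression, Normalizer
    Selection, GeNorm Stability and Delta-Delta-CT Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained pipeline for small-RNA-seq miRNA biomarker
    discovery and RT-qPCR validation: negative-binomial count simulation
    with planted differential expression and planted stable (normalizer-like)
    miRNAs, two-group differential expression with Benjamini-Hochberg FDR
    calling, multi-step endogenous-normalizer selection (FDR filter,
    fold-change proximity ranking, coefficient-of-variation screen, exclusion
    lists), GeNorm reference-gene stability (M values and pairwise-variation
    V curve), delta-delta-CT relative quantification with fold-regulation
    volcano classification, cross-platform concordance summaries, and
    hypergeometric pathway over-representation of score-filtered miRNA
    targets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
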