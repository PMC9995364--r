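Package: amltk
Title: Single-Cell Genotyping, Monosomy Scoring and Risk Stratification for AML
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal single-cell analyses of acute myeloid
    leukemia (AML). Implements single-cell NPM1 type-A mutation genotyping
    from 3' scRNA-seq reads (motif matching, UMI collapsing, per-cell calls
    and sequential cluster-based leukemia assignment), gene-set module
    scoring with chromosome-7 monosomy classification, item-test reduction
    of expression signatures to informative genes, cross-platform survival
    risk stratification via quartile-categorized lasso-penalized Cox
    models, hashtag-oligo (HTO) label refinement on 2-D embeddings,
    single-hit limiting-dilution frequency estimation, and Cohen's kappa
    similarity between gene sets. A seeded synthetic-data module generates
    every input with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    survival,
    mclust,
    rlang,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
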