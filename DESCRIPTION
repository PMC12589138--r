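Package: maturatlas
Title: Developmental Maturation Analysis of Single-Cell Atlases
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies cell-type maturation from developmental single-nucleus
    RNA-seq atlases. Implements centroid-distance maturation trajectories with
    monotonization and gradual/stepwise classification, nearest-neighbour
    maturity, reference-based cell-type label transfer with threshold
    assignment rules, pseudobulk time-course differential expression with
    spline trend fitting and trend clustering, signalling module and
    refinement scores, an inter- versus intra-group centroid-distance test for
    sex and genotype effects, and principal-curve pseudotime projection for
    developmental-delay detection. Includes a negative-binomial synthetic
    count generator with planted age trends, sex effects and genotype delays
    for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    limma,
    edgeR,
    fgsea,
    mgcv,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, DifferentialExpression, Software
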