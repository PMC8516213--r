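Package: trajDEG
Title: Trajectory Classification of Differentially Expressed Genes in
    Longitudinal RNA-seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-group longitudinal bulk RNA-seq
    time courses: counts-per-million filtering and TMM normalization,
    per-timepoint negative-binomial differential expression (quasi-likelihood
    F-test via edgeR), construction of per-gene log fold-change trajectories
    across timepoints, classification of genes into short-term (dissipating)
    and late-onset differentially expressed sets, a nonparametric trend-test
    battery (Mann-Whitney, Kruskal-Wallis, Jonckheere-Terpstra) on pooled
    trajectories, and hypergeometric gene-set overrepresentation. Includes a
    negative-binomial simulator that plants trajectory archetypes with a
    machine-readable ground truth so every stage of the pipeline can be
    validated without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    pheatmap
Config/testthat/edition: 3
biocViews: RNASeq, DifferentialExpression, TimeCourse, GeneExpression,
    Normalization, GeneSetEnrichment
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
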