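Package: pipegrid
Title: Combinatorial Benchmarking of Multi-Step Analysis Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A declarative framework for benchmarking multi-step analysis
    pipelines across all combinations of per-step parameter alternatives.
    Distinct pipeline prefixes are executed exactly once (prefix sharing),
    evaluations and wall times are collected on the fly, and results are
    aggregated into tidy per-step tables. Ships a self-contained single-cell
    RNA-seq evaluation suite: a seeded synthetic count-data generator with
    known subpopulations, doublets and low-quality cells; per-cell QC metrics
    and MAD-based filter sets; cluster-informed artificial-doublet detection
    with ROC evaluation; reference processing stages (log-normalization,
    feature ranking including binomial deviance, PCA, neighbor graphs, graph
    clustering); clustering metrics (ARI, mutual information,
    Hungarian-matched F1); truth-based intermediate metrics (variance and
    deviance explained, adjusted covariate correlations); and dimensionality
    estimators (elbow via farthest point, jackstraw-style permutation,
    molecular cross-validation).
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    MASS,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    pROC
Config/testthat/edition: 3
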