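Package: tdfe
Title: Tensor-Decomposition-Based Unsupervised Feature Extraction for
    Paired Omics Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates two omics layers (e.g. mRNA and miRNA expression)
    measured on the same samples by building an implicit three-way tensor,
    collapsing it over samples, and extracting matched singular components
    across the two feature spaces. Components whose per-layer sample
    projections separate a binary phenotype are identified with Welch
    t-tests and cross-layer Pearson correlation, and features are selected
    by chi-squared scoring of singular-vector entries with
    Benjamini-Hochberg false-discovery-rate control. Includes the
    principal-component-analysis variant of the same feature-extraction
    scheme, a supervised Welch t-test baseline, miRNA-mRNA pair-correlation
    analysis, cross-dataset concordance testing via a 2x2 confusion table
    and Fisher's exact test, readers for tab-separated expression matrices
    and GEO series-matrix files, and a synthetic paired-omics generator
    with planted class-driven signal features for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
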