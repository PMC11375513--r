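Package: microcca
Title: Sparse Canonical Correlation Integration of Airway Transcriptome
    and Microbiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Paired integration of sputum gene-expression and microbial
    relative-abundance profiles via lasso-penalized sparse canonical
    correlation analysis (penalized matrix decomposition). Provides the
    filtering stages that define the feature space (differential-expression
    gating, per-group variance filtering, abundance/prevalence filtering,
    centered log-ratio transform), alternating soft-threshold PMD updates
    with deflation for multiple components, cross-validated penalty tuning,
    permutation-based component-count selection, Fisher's exact pathway
    enrichment of component genes, a kernel-ECDF rank-random-walk per-sample
    enrichment score (GSVA-style), Spearman correlation of component and
    enrichment-score signals with clinical traits, and a synthetic-data
    generator with planted sparse components for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    fgsea,
    knitr,
    rmarkdown
Config/testthat/edition: 3
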