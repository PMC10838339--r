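Package: itgact
Title: T Cell Activation Scoring and Integrin Subset Analysis for RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying T cell activation and triple-integrin
    (ITGB7/ITGB1) T cell subsets in transcriptomic data from Crohn's disease
    cohorts. Implements a five-gene above-median T cell activation score with
    high/low patient stratification for paired two-timepoint bulk RNA-seq,
    stratified cytotoxic-gene contrasts, ROUT robust outlier removal with
    normality-dispatched two-group testing, median-of-ratios size-factor
    normalization, and a single-cell workflow (QC, PCA/UMAP/Leiden clustering,
    integrin subset classification, cluster enrichment, cluster-vs-rest marker
    ranking, expression-signature summaries). Includes negative-binomial bulk
    cohort and UMI-level single-cell simulators with ground truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    data.table,
    igraph,
    FNN,
    uwot,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
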