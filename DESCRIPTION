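Package: pathmarker
Title: Pathway-Gene Biomarker Discovery from Joint Preclinical and Clinical Expression Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-mining pipeline for deriving pathway-gene biomarkers that
    jointly predict preclinical drug sensitivity (IC50 across tumor cell lines)
    and clinical outcome (months to progression of treated patients) from
    baseline gene expression. Implements random subset sampling of linear ridge
    regression models with automatic ridge-parameter selection and dual p-value
    filtering, aggregation of accepted models into candidate gene lists,
    overlap gene-set enrichment with FDR control, a signed Kruskal-Wallis
    pathway fitness score with leave-one-out gene contributions, biomarker
    panel selection, random-forest prediction-error and AUC evaluation, a
    pooled t-statistic per-patient classifier, and network export of the
    resulting pathway-gene biomarkers. A synthetic-data generator with a
    planted driver signature makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    xml2,
    randomForest,
    pROC
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
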