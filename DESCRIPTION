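Package: inflamark
Title: Knowledge-Driven Prediction and Cohort Verification of Blood-Based
    Markers of Liver and Adipose Tissue Inflammation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanism-based workflow that prioritizes candidate blood
    protein biomarkers of low-grade inflammation in liver and white adipose
    tissue. Tissue-related gene sets are assembled from an ontology DAG by
    keyword search, curation and descendant expansion, intersected with
    immune-process gene sets, extended with tissue-enriched genes called
    from a cross-tissue expression atlas (four-fold rule), and filtered
    against a blood protein-biomarker knowledgebase with a novelty rubric.
    Candidates are then verified in a high-fat-diet mouse cohort via
    negative-binomial Wald differential expression with Benjamini-Hochberg
    correction, Spearman correlation of expression to histological
    inflammation scores, and a literature confirmation-level rubric. A
    synthetic-data module generates every input with planted ground truth
    so the full pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
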