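Package: metafork
Title: Metabolic Fork Screening and Regulatory Circuit Assembly from
    Two-Condition Multi-Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects condition-dependent metabolic branch points
    ("metabolic forks") from paired metabolome and transcriptome
    abundance tables measured under two conditions. Candidate triplets
    (A, B, C) are screened by the change in Pearson correlation between
    a focal feature A and the log-ratio of a feature pair B/C across
    conditions, validated with bidirectional linear models carrying a
    condition-by-predictor interaction term, and merged into annotated
    regulatory circuit graphs when validated forks share members.
    Includes minimum-value imputation and log transformation for
    metabolite data, Welch two-sample tests for differential abundance
    and expression, GraphML/JSON/TSV circuit export, and a synthetic
    two-condition multi-omics generator with planted forks for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
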