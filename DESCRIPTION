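Package: pleioscan
Title: Multi-Trait Subset Scanning for GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("pleioscan", "developers", email = "pleioscan@example.org",
           role = c("aut", "cre"))
Description: Identifies the most anomalous subset of traits associated with a
    single genetic variant (or a weighted genetic score) from per-trait GWAS
    summary statistics. Per-trait z-scores are decorrelated by ZCA-cor
    whitening against a null-SNP z-score correlation matrix, scanned with
    higher-criticism and truncated chi-squared score functions using a
    linear-time subset scan, and calibrated against Monte-Carlo (or, for
    higher criticism, analytic) null distributions. Includes a genetic-score
    extension that rebuilds score-level association statistics from per-SNP
    summary data and a reference panel, a PheWAS minimum-p baseline, and a
    synthetic-data simulator with power and trait-selection metrics.
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
    optparse
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
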