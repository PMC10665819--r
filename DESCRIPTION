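Package: metabonet
Title: Metabolomics Statistics, Differential Correlation Patterns, and
    Reporter-Metabolite Network Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolchain for quantitative tissue metabolomics with a
    matched transcriptome: probabilistic quotient normalization and
    Mann-Whitney screening of metabolite concentration tables, per-group
    Pearson correlation pattern mining across wildtype, disease and treated
    groups, constrained one- and two-step path finding on a stoichiometric
    reaction network with half-reaction decoupling and hub exclusion, and a
    weighted Fisher reporter-metabolite statistic that projects gene-level
    differential-expression p-values onto substrate-product metabolite ratios.
    Includes a seeded synthetic-data generator (toy stoichiometric models,
    three-group concentration tables with implanted correlation patterns, and
    gene statistics with planted signal) so every stage is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
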