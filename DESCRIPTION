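Package: plexfactor
Title: Multifactorial Analysis of 8-Plex Isobaric-Label Proteome Ratio Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multifactorial comparative analysis of isobaric-label
    (iTRAQ 8-plex) protein quantification tables arranged as a 2x2x2 factorial
    design (e.g. ethanol diet x CYP2E1 knockout x gender). Implements fold
    change / p-value significance filtering with between-condition overlap
    analysis, principal component analysis with Hotelling T-squared ranking of
    extreme proteins, one-way ANOVA with Tukey-Kramer multiple comparison of
    observation means, complete-linkage hierarchical clustering of
    observations, K-means clustering on a deviation-from-equal-expression
    distance to detect factor interactions, and an open upstream-regulator
    activation score (activation z and hypergeometric overlap p) driven by
    user-supplied signed regulator-target networks. Includes a synthetic-data
    generator that emulates the factorial channel layout with known ground
    truth, and a pipeline orchestrator with reproducible manifests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
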