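Package: diabesity
Title: Decomposition and Phenome-Wide Comparison of Concordant and
    Discordant Obesity-Diabetes Genetic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to split body-mass-index-raising genetic variants into
    diabetes-concordant and diabetes-discordant profiles from paired GWAS
    summary statistics and to compare the two profiles phenome-wide.
    Implements summary-statistics harmonization, LD clumping and proxy
    search, Paule-Mandel random-effects pooling with a profile
    difference (delta) test, shadow-feature random-forest relevance
    selection, single-linkage outlier detection, unweighted genetic risk
    scores with phecode, laboratory, survival and extreme-decile
    association batteries, summary-based Mendelian randomization with the
    HEIDI heterogeneity test, tissue-of-action scoring, and directional
    instrument decomposition. A synthetic-data generator with recorded
    ground truth makes every stage testable without access to cohort or
    consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    ranger,
    survival,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR
Config/testthat/edition: 3
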