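Package: grsens
Title: Gene-Environment Screening and Genetic Sensitivity Scores for Body-Fat Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens a candidate SNP panel for gene-environment interactions
    with changes in carbohydrate intake, fat intake, total calorie intake and
    exercise status on body-fat change; prunes linkage-disequilibrium
    redundancy; builds signed, unweighted genetic risk scores per intervention
    category; stratifies individuals into quartile sensitivity classes; and
    evaluates class-wise body-fat change in responder subgroups. Includes a
    seeded synthetic cohort generator with Hardy-Weinberg genotypes, optional
    LD blocks, longitudinal diet and exercise phenotypes, and configurable
    planted main and interaction effects, so the whole pipeline is testable
    without restricted cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
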