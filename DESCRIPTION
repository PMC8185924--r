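Package: crohnsig
Title: Tissue-Specific Gene Signatures Discriminating Colonic from Ileal Crohn's Disease
Version: 0.1.0
Authors@R:
    person("crohnsig", "maintainers", email = "crohnsig@example.org", role = c("aut", "cre"))
Description: A pipeline for characterizing and discriminating colonic Crohn's
    disease (CCD) from terminal-ileal Crohn's disease (ICD) using bulk
    expression matrices on the FPKM scale. Implements adaptive two-group
    testing (Shapiro/Levene gated t-test versus Wilcoxon rank-sum), a 95
    percent confidence-interval non-overlap filter for differentially
    expressed genes, four-comparison tissue-specificity classification into
    colonic (CCG) and ileal (ICG) disease genes, a six-type expression-pattern
    taxonomy, ulcerative-colitis characteristic filtration, repeated
    single-gene logistic-regression feature selection with k-fold
    cross-validation, and a random-forest discriminator reporting accuracy,
    AUC, PPV and NPV. A seeded synthetic-cohort generator with planted gene
    classes provides a known truth set for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
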