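Package: vmcst
Title: Community State Typing and Diversity Analysis of the Vaginal Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 16S rRNA profiles of the vaginal microbiota:
    rarefaction-based alpha diversity (observed taxa, Chao1, Shannon in bits),
    Bray-Curtis beta diversity with principal coordinates analysis and a
    permutational multivariate analysis of variance (PERMANOVA) engine with
    exhaustive-enumeration support, gap-statistic estimation of the number of
    community clusters with k-means, rule-based community state type (CST)
    assignment including CST IV sub-clusters, Lactobacillus-dominance
    classification, Nugent scoring from Gram-stain morphotype quantitation, and
    a morphotype/16S top-5-genera concordance statistic. Includes a seeded
    Dirichlet-multinomial cohort generator that emulates the group structure of
    a sex-worker/non-sex-worker study population so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vegan,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    readxl
Config/testthat/edition: 3
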