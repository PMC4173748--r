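Package: cdlsmosaic
Title: Cohort Phenotype Analysis and Mosaicism Estimation for Cornelia de
    Lange Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for Cornelia de Lange syndrome (CdLS) cohort
    studies: facial gestalt score aggregation with inter-rater concordance
    checks, mutation-yield summaries under a truncation reporting convention,
    CART-style classification trees over growth and phenotype features with a
    two-threshold filter that flags probable undetected NIPBL mosaics among
    mutation-negative cases, landmark-based average-face construction
    (generalized Procrustes analysis, Delaunay reference mesh, piecewise
    affine appearance warping), and variant-allele-fraction quantification of
    somatic mosaicism with Wilson score intervals. Includes synthetic cohort
    and face-image generators so every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
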