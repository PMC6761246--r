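Package: lipidtriad
Title: Trans-Compartment Lipidomics of Mother-Milk-Infant Triads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for direct-infusion mass-spectrometry (DIMS)
    lipid profiles measured in linked maternal plasma, breast milk and infant
    plasma samples. Annotates m/z signals against a lipid species library with
    a ppm mass-accuracy window, performs blank subtraction, isobar
    aggregation, presence filtering and per-mode total-signal normalization,
    compares mothers and infants with a square-root-corrected significance
    threshold, builds a cross-compartment Pearson correlation chain for
    candidate growth biomarkers, bi-clusters analytes and individuals with a
    multinomial Dirichlet-process Bayesian hierarchical clustering model
    (a latent structure model), and scores marker enrichment within clusters.
    Includes a seeded synthetic mother-milk-infant cohort generator with
    planted correlations and feature clusters so that every stage is testable
    without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    ape,
    yaml,
    optparse
Config/testthat/edition: 3
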