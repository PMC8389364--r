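Package: flychoice
Title: Photopreference Choice Assays, Countercurrent Fractionation and
    Walking-Trajectory Metrics for Drosophila
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of Drosophila photopreference
    experiments: the elevator-corrected Choice Index for light/dark T-maze
    sessions, the Performance Index for Benzer's countercurrent phototaxis
    paradigm, exact binomial and beta-binomial models of countercurrent
    fractionation with maximum-likelihood fitting and posterior-predictive
    retest curves, eight walking-trajectory metrics for Buridan's paradigm,
    and a nonparametric statistics layer (Kruskal-Wallis with Dunn post-hoc,
    Levene and Shapiro-Wilk checks, correlation-matrix PCA with eigenvalue-1
    retention). A seeded synthetic-behavior generator simulates fly
    populations under competing spontaneity (shared choice probability) and
    individuality (latent heterogeneous preference) models so that every
    stage of the pipeline can be exercised and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
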