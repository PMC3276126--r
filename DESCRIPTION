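Package: qstreml
Title: Quantitative Genetic Divergence and Heritability from
    Open-Pollinated Progeny Trials
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative-genetic analysis of open-pollinated
    provenance/progeny trials laid out as resolvable incomplete block
    designs.  Estimates variance components by restricted maximum
    likelihood (REML) for univariate and bivariate individual-tree models;
    derives narrow-sense heritability, additive and population-level
    coefficients of genetic variation, and Qst with delta-method standard
    errors; tests Qst against a marker-based Fst with a one-tailed
    boundary-corrected likelihood-ratio test; estimates additive-genetic,
    population and phenotypic correlations from bivariate fits; regresses
    population means on latitude of origin; and simulates trials with
    known truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
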