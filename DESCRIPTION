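Package: camtrapgrad
Title: Camera-Trap Mammal Community Analysis Along Urbanization Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for citizen-science camera-trap surveys of
    mammal communities along urban-wild development gradients. Collapses
    photo streams into independent detection sequences, builds daily
    detection histories, computes detection rates and naive occupancy,
    estimates incidence-based Hill-number diversity (richness and Shannon)
    with rarefaction confidence intervals, fits Bayesian Poisson models of
    detection counts with camera-night offsets, fits a multispecies
    occupancy model with multivariate-Bernoulli latent states and
    imperfect detection, runs posterior predictive checks with squared
    Pearson residuals and Bayesian p-values, and compares marginal
    occupancy distributions across strata and studies via interquartile
    overlap. A synthetic survey generator with known ground truth makes
    every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
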