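Package: dieldecline
Title: Diel-Niche Variation in Mammalian Population Decline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative analysis of population decline across diel niches
    (nocturnal, crepuscular, cathemeral, diurnal). Provides rule-based
    classification of Red List style population trends and anthropogenic
    threats, phylogenetic logistic regression by maximised penalised
    likelihood, phylogenetic Poisson generalised estimating equations,
    Mk-model imputation of diel niche, repetition of every model over a
    posterior sample of phylogenies with robustness-tier aggregation,
    equal-area mapping of proportional declines, and a synthetic-data
    generator producing complete study-shaped inputs with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
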