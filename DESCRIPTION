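Package: agematch
Title: Spatio-Temporal Matching of Population Ageing and Medical Resources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how regional medical resources keep pace with
    population ageing on areal region-by-year panels. Provides global, local
    and bivariate Moran spatial autocorrelation with conditional permutation
    inference and LISA cluster labelling; a Bayesian spatio-temporal effects
    model (Leroux conditional autoregressive spatial effects, random-walk
    temporal effects, independent space-time interactions) estimated by
    Markov chain Monte Carlo with Geweke convergence checks; the indicator of
    ageing-resources (IAR), an odds-ratio based composite measuring how well
    health institutions, beds and technical personnel match the elderly
    population ratio, with weighted kernel density surfaces; and a hybrid
    forecaster combining Holt linear exponential smoothing with a neural
    network fitted to its residuals. A seeded synthetic-data generator
    produces panels and adjacency structures with known spatial, temporal and
    interaction effects so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
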