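Package: budchill
Title: Chilling Requirement Estimation and Candidate Gene Screening for
    Bud Dormancy Release
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating the chilling requirement (CR) of
    perennials from hourly winter temperature records, built around the
    chill-hour (0-7.2 degree band) and linear chill-unit weighting models.
    Estimates CR brackets from natural and artificial (refrigerated
    storage) chilling experiments with morphology-based adequacy rules,
    intersects evidence across experiments, and applies the models in
    reverse to date the CR-fulfillment period of a winter and its
    between-year delay. Also screens temperature- and
    photoperiod-associated candidate genes from annotated FPKM expression
    matrices, quantifies qPCR measurements by the 2^-deltaCt method, and
    tests whether between-winter shifts in six-checkpoint expression
    profiles are congruent with the CR-fulfillment delay. Includes seeded
    synthetic-data generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
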