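Package: pbfit
Title: Percentage Body Fat Prediction from Segmental Bioimpedance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts percentage body fat (PBF) from segmental
    bioelectrical-impedance and anthropometric measurements. Candidate
    features built from eight segmental impedances, gender, age, weight and
    height are ranked by an RReliefF variant whose neighbour metric combines
    a normalized Euclidean distance with a correlation-based morphological
    distance, then reduced by minimum-redundancy maximum-relevance (mRMR)
    selection. The coefficients of the resulting linear PBF model are solved
    by a real-coded modified adaptive genetic algorithm with a grouped
    elitism/roulette/discard selection operator. Includes a synthetic BIA
    cohort generator with known ground truth for recovery experiments, and
    a command-line interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    class
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    readxl
Config/testthat/edition: 3
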