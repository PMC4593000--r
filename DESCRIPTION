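Package: qfascreen
Title: Quantitative Fitness Analysis for Genome-Wide Yeast Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative fitness analysis (QFA) of arrayed microbial cultures:
    fits the generalized logistic growth model to colony density time courses,
    derives maximum doubling rate (MDR), maximum doubling potential (MDP) and
    their product as a scalar fitness, estimates genetic interaction strength
    of a query screen against a control screen under Fisher's multiplicative
    model with Welch t-tests and Benjamini-Hochberg false discovery rate
    control, strips genes linked to the query locus, classifies interactors
    into Venn areas across screens, and ranks genes by fitness-profile
    similarity. Includes a synthetic screen generator with known ground truth
    so the whole pipeline can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
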