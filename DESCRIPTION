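Package: dimorph
Title: Geometric Morphometrics of Facial Sexual Shape Dimorphism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical shape analysis of sexual dimorphism in 2D landmark
    data. Implements generalized Procrustes superimposition with
    bending-energy semilandmark sliding and bilateral symmetrization, the
    sexscore projection of individual shapes onto the male-minus-female
    mean axis, decomposition of sexual shape dimorphism into allometric
    and non-allometric components with the associated vector angles,
    trajectory analysis of sex-difference vectors across populations,
    Procrustes-variance morphological disparity, stratified permutation
    and split-sample tests, mixed-effects models of attractiveness
    preferences, quadratic-approximation Bayesian regression, and a
    synthetic multi-population face generator with known ground truth.
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
    jsonlite,
    lme4,
    lmerTest,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
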