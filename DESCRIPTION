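Package: braidr
Title: Bounded-Rational Analysis of Hierarchical Absolute Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for information-theoretic bounded-rationality analysis of
    hierarchical absolute identification tasks. Implements a Blahut-Arimoto
    solver for the utility/information trade-off over a twelve-state,
    twenty-one-action response hierarchy, efficiency frontiers and
    abstraction-level statistics, a family of constrained inefficiency models
    (fixed action priors, distorted and similarity-blurred utilities, Gaussian
    response profiles, Thurstonian and Binomial perceptual transducers),
    plug-in estimators for behavioral trial data, grid-search model fitting
    with k-fold cross-validation, a synthetic-cohort trial generator, and a
    dot-motion ellipse stimulus simulator with an automatic recognition
    algorithm.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
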