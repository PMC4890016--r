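Package: facedcm
Title: Effective Connectivity Analysis of the Bilateral Face Perception Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modelling pipeline for handedness studies of the six-region
    bilateral core face perception network (early visual cortex, occipital face
    area and fusiform face area in both hemispheres). Implements the block
    paradigm and GLM regressor construction, a bilinear dynamic causal model
    with a balloon-windkessel haemodynamic observation model, enumeration of a
    96-model space organised in six families, variational Laplace model
    inversion with the negative free energy as log-evidence approximation,
    random-effects Bayesian model selection at model and family level,
    Occam's-window Bayesian model averaging, group statistics (t-tests with
    FDR correction within parameter classes, mixed ANOVAs, bootstrap
    lateralization index), pupillometry preprocessing with a per-block
    slow-change metric, and a fully seeded synthetic cohort generator so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
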