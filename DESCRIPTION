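Package: antiphony
Title: Quantifying Antiphonal Vocal Exchange in Paired Animals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying vocal turn-taking (antiphonal calling)
    between paired individuals recorded on separate channels. Provides a
    synthetic generator of coupled calling point processes with known ground
    truth, amplitude-envelope segmentation and spectro-temporal feature
    extraction of calls, model-based call-type clustering, cross-correlogram
    construction with Poisson baseline confidence limits, answer/answered
    counting and a directionality index of the exchange, integration with
    video-scored behaviour states (time budgets and per-state calling rates),
    and a Bayesian-flavoured inference layer: maximum-likelihood linear mixed
    models with posterior simulation under flat priors, derived posterior
    p-values, Lessells-Boag repeatability, and marginal/conditional R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    lme4,
    MASS,
    mclust,
    signal,
    yaml,
    readr,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
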