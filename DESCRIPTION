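Package: ikrfit
Title: Multi-Protocol Fitting and Validation of Markov Models of the Cardiac
    Potassium Current IKr
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating Markov models of the rapid delayed rectifier
    potassium current (IKr, carried by hERG/KV11.1 channels) against
    voltage-clamp data from many experimental designs. Provides four literature
    model structures, a voltage-clamp protocol engine with the common leak-ramp
    and reversal-ramp scaffolding, a hybrid matrix-exponential/stiff-ODE
    simulator, a synthetic-data generator emulating automated patch-clamp
    experiments (linear leak, voltage offset, IID Gaussian noise, well-level
    heterogeneity), trace postprocessing (leak correction, drug subtraction,
    reversal-potential inference, quality control), repeated CMA-ES
    maximum-likelihood fitting, cross-protocol validation metrics (NRMSE,
    fit/prediction errors, ensemble consistency), and a two-way fixed-effects
    linear model quantifying well- and protocol-dependence of parameter
    estimates via log-likelihood differences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
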