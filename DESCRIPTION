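Package: gxemaize
Title: Genotype-by-Environment Interaction and Yield Stability of Maize
    with a Thermal-Time Crop Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying genotype-by-environment interaction (GEI)
    and yield stability in maize multi-environment trials, together with a
    desk-scale daily crop simulator in the CERES-Maize tradition so that
    simulated yields can be analysed alongside observed ones.  Includes a
    stochastic weather generator for dry- and wet-savanna rainfall regimes, a
    synthetic yield-trial generator with controllable variance structure,
    model-evaluation statistics (Willmott d-index, Nash-Sutcliffe model
    efficiency, RMSE, bias), balanced two-way ANOVA variance partitioning,
    Finlay-Wilkinson joint regression, Wricke ecovalence, Shukla stability
    variance, AMMI decomposition with the AMMI stability value, the Kang
    yield-stability rank-sum index, AICc model comparison, and rank
    concordance between observed and simulated stability reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
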