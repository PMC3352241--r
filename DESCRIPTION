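Package: alcopaf
Title: Population-Level Alcohol Exposure Distributions and Attributable Fractions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for modelling population-level alcohol consumption from
    survey microdata and propagating it into burden-of-disease estimates.
    Fits Log-Normal, Gamma and Weibull consumption distributions to
    drinker-level grams-per-day data by maximum likelihood (Newton-Raphson on
    the profile likelihood), computes categorical and continuous
    Population-Attributable Fractions (PAFs) under pluggable relative-risk
    curves with trapezoidal integration, characterizes the Gamma distribution
    through the sex-specific linear relationship between its mean and standard
    deviation, and upshifts a fitted Gamma exposure distribution to per-capita
    consumption figures so that the whole distribution can be recovered from
    average consumption alone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    lmtest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
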