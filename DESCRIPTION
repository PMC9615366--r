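Package: rerpgrid
Title: Mass Univariate Regression ERP Estimation on Time-by-Channel Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits ordinary least-squares regression models at every (time,
    channel) cell of event-locked multi-channel time series (regression ERPs),
    exposing the complete per-cell fit statistics -- coefficients, standard
    errors, residuals, likelihood, AIC, influence diagnostics -- as tidy
    time-series grids. Includes a Wilkinson-style formula compiler with
    treatment coding, polynomial and B-spline transforms, mass model comparison
    by AIC and likelihood-ratio tests, a wide continuous-data formulation that
    verifies coefficient identity with segmented per-time-point fits, and a
    synthetic event-related data generator with known coefficient waveforms for
    end-to-end testing without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    splines,
    ggplot2,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
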