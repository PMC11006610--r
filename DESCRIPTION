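Package: commtrend
Title: Biodiversity Trends in Long-Term Community Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating biodiversity change from long-term,
    unevenly sampled community monitoring data, built around insect
    assemblage surveys. Standardizes sampling effort by resampling,
    cleans partial (genus-level) identifications, computes
    abundance-, richness-, coverage- and entropy-based diversity
    metrics, bins species abundance distributions into abundance
    intervals, fits hierarchical autoregressive year-trend models
    (Gaussian, beta and Poisson families), corrects population trends
    for regression-to-the-mean via left-censoring, and simulates
    community time series with known ground-truth trends for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmmTMB,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr
Config/testthat/edition: 3
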