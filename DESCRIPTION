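Package: citysurv
Title: Spatio-Temporal Surveillance and Grey Forecasting of District-Level
    Hospitalization Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-area hospitalization surveillance on annual
    district panels: crude and indirectly standardized admission rates with
    rank classification and interval change patterns, mean-center and
    standard-deviational-ellipse summaries of case point clouds, a
    retrospective space-time scan statistic (discrete Poisson model,
    cylindrical windows, Monte-Carlo inference), and GM(1,1) grey-model
    forecasting with posterior-deviation validation and per-hospital burden
    projection. Includes a seeded synthetic-data generator emulating a
    ten-district, ten-year urban study design, plus an end-to-end pipeline
    with CSV/GeoJSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
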