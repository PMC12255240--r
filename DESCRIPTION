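Package: kneeload
Title: Medial Tibiofemoral Contact Force Estimation from Joint Moments and
    Ultrasound Knee Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduction-model pipeline for estimating peak medial tibiofemoral
    joint contact force (MJCF) during walking, running and sit-to-stand
    movements. Conditions force-plate and joint-moment time series with
    dual-pass Butterworth filters, segments trials into strides and
    sit-to-stand phases from formula-defined force thresholds, distributes net
    ankle, hip and knee moments to muscle-group forces in a fixed
    cross-sectional-area-proportional sequence, and evaluates the medial
    contact force by balancing moments about the lateral tibiofemoral contact
    point with an ultrasound-derived intercondylar lever arm. Includes a
    calibrated ultrasound tile-stitching and distance-measurement module,
    ICC(2,k) reliability statistics with standard error of measurement, gated
    two-group comparisons with Cohen's d and Bonferroni correction,
    noncentral-t power analysis, and synthetic-data generators with known
    ground truth for every stage.
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
    png,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
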