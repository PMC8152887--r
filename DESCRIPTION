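Package: oddballmeg
Title: Simulation and Cluster-Based Permutation Inference for Auditory Oddball MEG Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying children's magnetoencephalographic (MEG)
    responses to phonological oddballs. Simulates oddball stimulus trains,
    sensor layouts, socioeconomically diverse cohorts with a planted
    behavioral factor structure, and evoked sensor-by-time fields with known
    effects; builds deviant-minus-standard mismatch contrast fields; reduces
    behavioral batteries with principal components, varimax rotation and
    Horn's parallel analysis; constructs OECD-equivalized income and
    subjective socioeconomic-status covariates; fits a mass ordinary
    least-squares general linear model at every (sensor, time) point; and
    performs spatio-temporal cluster-based permutation inference with
    sign-flip and regressor-shuffle null distributions under max-statistic
    family-wise error control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
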