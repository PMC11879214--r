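Package: espcover
Title: Unsupervised Detection of Effect-Size-Profile Modifiers with
    Overlapping Covariate Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects covariates that modify the joint effect-size profile
    (ESP) linking many omics exposures to a single outcome. The covariate
    space is covered with overlapping, data-driven gliding windows; a
    per-window ESP is estimated by univariate regression (linear slopes or
    logistic odds ratios, optionally confounder-adjusted); windows are
    clustered in standardized ESP space with agglomerative clustering; the
    number of clusters is chosen by a four-index vote and tested against a
    one-cluster null using a uniform reference-dataset elbow statistic.
    Includes generators for the benchmark synthetic designs (no
    modification, two regions, three regions) with ground-truth region
    labels, and a Monte-Carlo validation driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
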