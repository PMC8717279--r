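Package: trackfda
Title: Functional Data Analysis of Animal Telemetry and Movement Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Smooths irregular GPS telemetry with penalized B-splines on a
    unified refined time grid, with kernel-density-guided knot placement and
    generalized cross-validation for the roughness penalty. From the fitted
    movement curves it derives metric speed and rest-period densities,
    pairwise WGS84 geodesic distance series and cooccurrence-potential
    densities, and a localized mutual information function quantifying
    time-varying association between pairs of animals. Includes an
    Ornstein-Uhlenbeck telemetry simulator with scheduled association
    windows for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
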