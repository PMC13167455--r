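Package: rangecomp
Title: Group Size, Space Use and Between-Group Competition in Social Primates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how group size and climate anomalies shape
    within- and between-group resource competition in group-living animals.
    Provides a synthetic study-system generator with known ground truth
    (demography, riparian landscape with RED/NIR imagery, seasonal climate
    anomalies, Ornstein-Uhlenbeck space use, focal foraging counts, and
    model-generated dyadic outcomes); NDVI compositing and zonal statistics;
    kernel utilization distributions, home-range contours, daily path length
    and revisitation rates; dyadic proportional-overlap and encounter-rate
    metrics with range-shift attribution; and Bayesian inference via JAGS for
    group-level GLMMs (negative binomial, gamma, beta; offsets and
    measurement error), a hurdle-beta social relations model for directed
    overlap, and a symmetric multiple-membership model for encounter rates,
    summarized with 89% highest posterior density intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    coda,
    rjags,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    glmmTMB,
    ggplot2
Config/testthat/edition: 3
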