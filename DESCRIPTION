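Package: weanpoint
Title: Weaning-Age Estimation from Trace-Element Transects Across Tooth Cementum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates mammalian age-at-weaning from calcium-normalized
    strontium and barium concentration transects ablated across tooth
    cementum. Provides below-detection-limit substitution, outlier removal
    and Savitzky-Golay smoothing of laser-ablation transects; registration
    of transect distance onto a continuous growth-layer coordinate;
    continuous piecewise-linear (segmented) regression with an iterative
    breakpoint-update fitter and an exhaustive grid-search oracle;
    classification of element-accumulation patterns; per-animal weaning
    layer assignment and cohort-level weaning distributions, agreement and
    sex-comparison statistics; and a seeded synthetic-cohort generator with
    known ground truth for parameter-recovery validation.
License: MIT
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
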