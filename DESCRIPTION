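Package: taperlab
Title: Modelling Training Responses of Swim Performance and Nocturnal
    Parasympathetic Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying daily swim-training load, extracting
    nocturnal heart-rate-variability band powers from RR-interval
    recordings via a maximal-overlap discrete wavelet transform, fitting
    Banister's two-antagonistic-component (fitness-fatigue)
    impulse-response model to weekly performance and weekly
    high-frequency (HF) power, and deriving the adaptation/fatigue
    influence series and the taper-timing indices t_n (days to recover
    baseline after a bout) and t_g (days to peak). Includes a synthetic
    season generator with known ground truth for end-to-end validation,
    cohort-level relationship fits (logarithmic HF-performance link,
    RR-HF saturation screen, timing correlations) and ggplot2/broom
    style interfaces.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
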