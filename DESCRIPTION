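Package: dyadsync
Title: Surrogate Synchrony Analysis of Dyadic Electrodermal Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying physiological synchrony between two
    interacting people from skin-conductance recordings. Provides
    preprocessing of raw electrodermal activity (adaptive artifact
    detection, zero-phase low-pass filtering, decimation to a common
    analysis rate), surrogate-based synchrony effect sizes from windowed
    lagged cross-correlations with in-phase/anti-phase polarity and
    patient-/therapist-leading decomposition, session-level inference
    (one-sample and paired t-tests, cluster-wise centering,
    random-intercept mixed models of synchrony on alliance and session
    scales, pre/post outcome regressions), and a synthetic dyad and study
    generator with known ground truth so every stage is verifiable by
    parameter recovery.
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
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
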