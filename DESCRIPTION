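Package: pulsebeam
Title: Heart Rate Variability from Impulse-Radio Ultra-Wideband Radar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Non-contact heart-rate-variability (HRV) analysis from impulse-radio
    ultra-wideband (IR-UWB) radar frame matrices. Implements the full processing
    chain from raw fast-time by slow-time complex frames to RR intervals and HRV
    indices: reference-bin phase compensation, slow-time band-pass filtering,
    CFAR-style per-second sedentary-movement detection, spectral selection of the
    vital fast-time bin, amplitude-ordered iterative peak detection, and time- and
    frequency-domain HRV indices (mean RR, SDNN, RMSSD, LF/HF). Includes a
    synthetic radar-scene simulator with known ground truth, radar-versus-reference
    agreement statistics (Pearson correlation, Bland-Altman limits of agreement,
    ICC(2,1)), and distress-group discrimination (VAS grouping, one-way ANOVA, ROC
    with top-left optimal threshold).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
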