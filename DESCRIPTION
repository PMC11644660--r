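Package: pulsemodal
Title: Multimodal Non-Contact Heart-Rate Estimation from Facial RGB Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for camera-based (remote photoplethysmography) heart-rate
    estimation. Extracts a blood-volume-pulse signal from per-frame facial RGB
    traces with the plane-orthogonal-to-skin (POS) projection and with green,
    chrominance (CHROM) and independent-component baselines; filters it with a
    zero-phase Butterworth bandpass; estimates heart rate from the dominant
    FFT frequency; derives eleven time- and frequency-domain signal features;
    and fuses them with physical attributes (age, gender, height, weight, BMI)
    in grid-searched support-vector and random-forest regressions with k-fold
    cross-validation, modality ablation, feature importances and partial
    dependence. A synthetic cohort and pulsatile-trace generator makes the
    whole pipeline testable without human-subject recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
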