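Package: qusresp
Title: Quantitative Ultrasound Biomarkers for Pre-Treatment Prediction of
    Chemotherapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting tumour response to neoadjuvant chemotherapy
    from pre-treatment quantitative ultrasound (QUS). Implements per-window
    spectral analysis of beamformed radiofrequency (RF) echo data (midband
    fit, spectral slope and intercept, Gaussian form-factor scatterer size
    and acoustic concentration, mean scatterer spacing, attenuation
    coefficient), parametric-map assembly with grey-level co-occurrence
    texture and core-to-margin contrast features, and an imbalance-corrected
    classification stage (class-balanced down-sampling, sequential floating
    forward feature selection with p-value initialisation, and shallow
    neural-network or k-nearest-neighbour models). A point-scatterer RF
    phantom simulator and a synthetic cohort generator with known ground
    truth make the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    nnet,
    class,
    MASS,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
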