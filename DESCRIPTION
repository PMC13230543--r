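Package: feesr
Title: Landmark-Driven Residue Quantification and Airway-Invasion
    Screening for FEES Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for fiberoptic endoscopic evaluation of
    swallowing (FEES) recordings that have been pre-processed with
    markerless pose estimation. Reads DeepLabCut-style landmark CSVs,
    applies frame-quality gates, enhances endoscopic frames (CIELAB
    adaptive equalization, HSV blue-dye boosting, denoising,
    sharpening), constructs glottic, pyriform-sinus and vallecular
    regions of interest from tracked landmarks, quantifies blue-dyed
    residue as a pixel fraction, classifies severity on the Yale
    Pharyngeal Residue Severity Rating Scale, flags penetration and
    aspiration with a 3x3 glottic grid rule, and computes the
    diagnostic-agreement statistics (sensitivity, specificity, Cohen's
    kappa, Fisher's exact test) used to validate such pipelines. A
    synthetic phantom generator provides ground-truth fixtures for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
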