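Package: acusleep
Title: Macro Sleep Stage Estimation from Nocturnal Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Non-contact sleep staging from single-channel audio of a night's
    sleep. Implements the full chain from 44.1 kHz PCM audio to a wake/REM/NREM
    hypnogram: adaptive spectral-subtraction noise suppression, a trainable
    frame-level detector of inhalation, exhalation and body-movement sounds,
    a 67-feature epoch representation, cascaded real-time and offline
    neural-network sleep-stage classifiers, and an eight-parameter sleep
    quality report. Ships a physiologically motivated night simulator
    (hypnogram plus stage-conditioned audio with ground-truth event labels)
    so the whole pipeline can be trained and evaluated without patient
    recordings, together with epoch-by-epoch agreement statistics (confusion
    matrices, Cohen's kappa, Lin's concordance correlation, Bland-Altman
    limits of agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
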