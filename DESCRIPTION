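Package: somadecode
Title: Somatotopic Decoding of Event-Related fMRI by Beta-Series MVPA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible multivoxel pattern analysis (MVPA) pipeline for
    decoding stimulated body locations from event-related BOLD fMRI.
    Provides a synthetic-data generator emulating a four-location
    somatosensory stimulation design (randomized trial order, jittered
    inter-trial intervals, gamma hemodynamic responses, autocorrelated
    noise), single-trial beta-series estimation by least squares with
    voxel-wise mean scaling, linear support-vector decoding with
    within-fold ANOVA-F feature selection and stratified cross-validation,
    permutation-based significance with false-discovery-rate correction,
    and spherical searchlight mapping with Monte-Carlo cluster-extent
    family-wise-error control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    pROC,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
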