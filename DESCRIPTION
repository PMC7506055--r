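Package: gazescreen
Title: Continuous Gaze-Tracking Oculomotor Assessment and Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardised oculomotor assessment from continuous target-tracking
    recordings. Generates random-walk tracking stimuli (smooth pursuit and
    saccadic conditions), detects and parameterises saccades from binocular
    gaze traces with an adaptive acceleration threshold, fits the saccadic
    main sequence with prediction bands, extracts an 80-dimensional
    spatio-temporal feature vector together with polar-binned directional
    saccade statistics, screens individuals against robust normative
    references via modified z-scores, and clusters cohorts with a
    PCA / t-SNE / k-means pipeline. A parametric synthetic-observer simulator
    (healthy, internuclear-ophthalmoplegia-like, parkinsonian-like profiles)
    provides ground truth for every analysis stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
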