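Package: pao2morph
Title: Morphology Discovery for Intra-Tidal PaO2 Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering discrete morphologies of within-breath
    (intra-tidal) arterial oxygen tension (PaO2) oscillations recorded during
    mechanical ventilation. Provides a synthetic cohort simulator for fast
    intra-arterial PaO2 and airway-pressure traces; change-point alignment of
    the PaO2 signal with the phases of ventilation; breath segmentation,
    linear detrending, per-timepoint median aggregation and standard-deviation
    normalization; exclusion filtering on signal trough, signal-to-noise ratio
    and alignability; functional principal component analysis on the dense
    canonical breath grid; Monte-Carlo AIC-guided Hartigan-Wong k-means
    clustering of principal component scores with progression ordering; and
    downstream statistics (progression regression, one-way ANOVA, chi-square
    tests, linear mixed-effects models, sensitivity analyses and a mechanical
    power utility).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
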