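Package: tepdi
Title: Divergence Index Statistics for TMS-Evoked EEG Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-parametric comparison of TMS-evoked EEG potentials (TEPs).
    Implements trial-level artifact rejection (EOG amplitude and fast-beta
    muscle power rules), baseline equalization by Wilcoxon rank-sum, a
    trial-mixing permutation null with max-statistic family-wise correction
    over time, the Divergence Index (the percentage of spatio-temporal
    samples at which two TEPs differ significantly), and ROC/Youden-index
    classification of change versus no-change session comparisons. Includes
    a synthetic TMS-EEG session generator with controllable stimulation
    site, intensity and coil-angle effects, pink-noise background, blink and
    muscle artifacts, and between-day drift, plus self-describing session
    and report file formats and an end-to-end study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
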