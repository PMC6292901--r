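Package: wmnet
Title: Maintenance and Manipulation Networks in Working-Memory fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a delayed recognition
    alphabetization working-memory task. Quantifies maintenance demand (set
    size) and manipulation demand (minimum sorting steps over four sorting
    algorithms), simulates titrated cohorts with trial-level behavior and
    ROI-level BOLD timeseries carrying ground-truth network structure, fits
    first-level GLMs with concurrent parametric delay modulators and VIF
    diagnostics, defines equal-size maintenance and manipulation networks from
    group parametric maps, estimates correlational psychophysiological
    interaction (cPPI) connectivity per difficulty level, and derives network
    segregation, reconfiguration, and brain-behavior correlation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
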