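Package: osatriage
Title: Pediatric Obstructive Sleep Apnea Triage Algorithms and Oximetry Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for triaging children referred for suspected obstructive
    sleep apnea (OSA) to otolaryngology (ENT) or pediatric respirology.
    Implements questionnaire screeners (four discriminative Pediatric Sleep
    Questionnaire items, restless-leg, reflux and nasal-obstruction screens),
    McGill oximetry scoring of raw overnight SpO2 traces (artifact rejection,
    desaturation-event detection, cluster counting), three published
    rule-based triage decision trees, diagnostic-performance evaluation
    (confusion matrix, sensitivity, specificity, likelihood ratios,
    diagnostic odds ratio, 2x2 and covariate-adjusted odds ratios), and a
    calibrated synthetic cohort generator so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    zoo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
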