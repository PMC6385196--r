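Package: hrvidh
Title: Predicting Intradialytic Hypotension from Intradialytic Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the monthly frequency of intradialytic
    hypotension (IDH) in hemodialysis patients from heart-rate-variability
    (HRV) recorded during a single dialysis session. Implements RR-interval
    preprocessing (20% ectopic-beat rule, 5-minute segmentation with
    early/middle/late phase selection), time- and frequency-domain HRV
    features (SDNN, RMSSD, Welch-periodogram VLF/LF/HF/TP band powers),
    phase-change (delta) features, negative-binomial (NB2) count regression
    of IDH frequency with univariate screening, variance-inflation and
    AIC/BIC model search, and paired comparison of model discrimination via
    ROC curves and DeLong's test. Includes a synthetic-data module that
    generates tachograms with known spectral structure and cohorts with
    known count-model parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    car
Config/testthat/edition: 3
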