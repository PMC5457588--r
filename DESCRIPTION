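Package: uefrailty
Title: Upper-Extremity Function Frailty Index and Score from Elbow-Motion
    Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to derive frailty assessments from a 20-second repetitive
    elbow flexion/extension test recorded with arm-worn angular-rate sensors.
    Extracts eight kinematic and kinetic outcomes (speed, flexibility, power,
    rise time, elbow moment, speed variability, speed reduction and flexion
    number) from elbow angular-velocity traces, fits proportional-odds
    ordinal logistic models of Fried frailty categories, runs the full index
    development pipeline (normality screening, univariate association,
    collinearity checks, forward stepwise selection by AIC, stratified
    10-fold cross-validation with ROC analysis), and builds a continuous
    0-1 frailty score by a Framingham-style points procedure. Includes a
    synthetic cohort and trace generator for end-to-end testing without
    subject data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    MASS,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
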