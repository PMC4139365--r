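Package: holterchaos
Title: Linear and Nonlinear Heart-Rate-Variability Analysis of 24-Hour
    Holter Beat Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for 24-hour ambulatory (Holter) beat
    annotation streams: ectopic-beat exclusion and construction of
    normal-to-normal (NN) interval series, time-domain heart-rate
    variability (SDNN, CV, rMSSD), autoregressive (Burg) spectral
    estimation with low-frequency/high-frequency band powers, nonlinear
    dynamics (detrended fluctuation analysis, Grassberger-Procaccia
    correlation dimension, Shannon entropy of recurrence diagonal line
    lengths), ventricular arrhythmia quantitation with time-of-day
    chi-square testing, and single-component cosinor rhythm analysis.
    Includes a seeded integral-pulse-frequency-modulation simulator that
    generates 24-hour beat streams with diurnal heart-rate rhythm,
    autonomic spectral modulation, fractal scaling, and a configurable
    morning surge of ventricular ectopy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
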