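Package: tremorband
Title: Band-Limited Spectral Analysis of Resting Hand Tremor from Wearable Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify resting hand tremor from short tri-axial
    accelerometer recordings. Reduces raw 100 Hz trials to the acceleration
    magnitude, trims the adaptation transient, demeans, and applies a
    dual-branch zero-phase Butterworth filter (10 Hz low-pass and high-pass)
    before estimating the one-sided power spectral density with a single
    full-length Hamming window. From the spectrum it extracts the band
    log-amplitude indicator L(f1,f2) (mean natural-log PSD) and the
    power-weighted mean frequency F(f1,f2) in the 2-4 Hz and 10-20 Hz bands,
    and analyses cohorts with 2x2 within-subject repeated-measures ANOVA
    (time x limb), Greenhouse-Geisser epsilon, partial eta squared, and
    Bonferroni-adjusted pairwise contrasts. A seeded synthetic-cohort
    generator with known ground truth supports calibration and power checks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    data.table,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
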