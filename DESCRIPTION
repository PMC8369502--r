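Package: cardiowave
Title: Beat Detection and Action-Potential-Duration Analysis for Optical
    Cardiomyocyte Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for plate-based fluorescence recordings of
    spontaneously beating cardiomyocytes, as used in high-throughput cardiac
    safety screens with human iPS-cell-derived atrial-like and
    ventricular-like myocytes. Detects beats in voltage-dye traces, measures
    beat rate, amplitude, upstroke and decay velocities, and pulse-width
    durations (PWD) at fixed repolarization fractions with Fridericia rate
    correction, averages them over a 30-second window, classifies
    arrhythmia-like events (early afterdepolarizations, irregular beating,
    arrest), and assembles percent-change dose-response and incidence tables
    with the accompanying statistics. A calibrated synthetic-trace simulator
    with full ground truth makes every stage verifiable without laboratory
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
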