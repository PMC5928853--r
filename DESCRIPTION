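Package: ppgsqi
Title: Optimal Filtering of Short Photoplethysmogram Signals via the
    Skewness Signal Quality Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting a preprocessing filter for short
    photoplethysmogram (PPG) records. Provides a bank of 90 digital filter
    configurations (nine families, ten orders each: moving average, median,
    Hamming-window and least-squares FIR, Butterworth, Chebyshev I/II,
    elliptic bandpass, and wavelet denoising), zero-phase forward-backward
    application, a skewness-based signal quality index with windowed record
    scoring, a benchmarking harness that ranks configurations by quality
    improvement across expert-graded record groups, and a synthetic PPG
    generator for excellent/acceptable/unfit quality grades.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
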