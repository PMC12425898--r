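Package: qwachron
Title: Quantitative Wood Anatomy Chronologies and Dendroclimatic Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds intra-ring sector chronologies of tracheid anatomy (cell
    lumen diameter and cell wall thickness) from per-cell measurement tables,
    computes the standard dendrochronological signal statistics (Rbar, EPS,
    SNR, lag-1 autocorrelation), standardizes ring-width series with a
    variance-stabilizing power transform and a cutoff-parameterized cubic
    smoothing spline, and screens monthly, seasonal-window and gridded-field
    climate correlations against temperature, precipitation and drought-index
    records. Includes a calibrated synthetic-data generator emulating a
    semi-arid juniper site so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
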