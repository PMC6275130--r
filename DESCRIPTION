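Package: scgpipe
Title: Seismocardiography Processing for Heartbeat and Respiration Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processing chain for single-axis chest-wall acceleration
    (seismocardiography) recorded by a wearable accelerometer. Separates the
    raw trace into cardiac and respiratory components with second-order
    Butterworth filters, estimates heartbeat and respiration rates from
    band-limited peak trains, computes a distribution-shape health statistic
    (length over modal height of the rate histogram) with three-class
    classification, and evaluates agreement against a reference rate series
    with Bland-Altman statistics. Includes a deterministic synthetic-signal
    generator with ground-truth event times so the full chain is testable
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
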