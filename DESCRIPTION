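Package: hovermill
Title: Flight-Mill Event-Stream Decoding and Migratory Flight Performance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes raw photointerrupter event streams from tethered insect
    flight mills into per-transition kinematics (speed, residual speed, and
    drag-corrected insect acceleration), segments trials into discrete flight
    events with a soft speed cut-off, and computes per-fly flight performance
    metrics including total distance, time-weighted mean speed, a spontaneous
    flight-initiation statistic, and a per-minute activity/speed time transect.
    Ships published Gamma log-link and Gaussian log-scale prediction models
    for hoverfly flight performance as versioned fixtures, evaluates them with
    orthonormal polynomial contrasts for ordinal covariates, fits Gamma GLMs by
    iteratively reweighted least squares for parameter recovery, and includes a
    ground-truth-labelled synthetic flight-mill simulator (bout schedules,
    transition rendering with arm drag, hardware noise, spin-down trials, and
    morphometrics) so the whole pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
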