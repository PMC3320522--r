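Package: crisisrepair
Title: Detection and Classification of Rupture-Repair Episodes in
    Session-Rating Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects temporary deteriorations of the therapeutic
    relationship (ruptures) and their repair in session-by-session rating
    series from psychotherapy courses. Implements three formal criteria -
    a quadratic-trend residual-outlier rule, a step-level
    decrease/increase rule, and a cumulative-decline crisis-repair rule
    that also captures gradual downward trends - plus a five-pattern
    taxonomy of episode shapes, frequency and length summaries, a seeded
    synthetic-course generator with planted episodes, and long-format CSV
    input/output with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
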