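Package: stepcoach
Title: Hybrid Personalized Activity Recommendations from Wearable Step Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for personalized physical-activity eCoaching from
    minute-level wearable sensor records. Classifies days into WHO-derived
    activity levels both by deterministic rules and by a feed-forward neural
    classifier, forecasts daily step counts with a one-dimensional
    convolutional network, wraps point forecasts in naive-residual prediction
    intervals, computes weekly activity-pattern statistics (pattern vectors,
    similarity and weighted performance scores, cumulative deviation), and
    turns these signals into recommendation messages through a propositional
    rule base with per-category exclusivity. Results can be annotated into a
    small activity-coaching knowledge schema and exported as RDF/Turtle. A
    seeded synthetic cohort generator emulates minute-epoch accelerometer
    output so the full pipeline runs without any real dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
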