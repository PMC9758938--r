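Package: photobeam
Title: Closed-Loop Light Stimulation and Beam-Crossing Activity Analysis for
    Fly Tube Monitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A virtual closed-loop light-stimulation rig for Drosophila housed
    in multi-beam activity tubes, together with the behavioural analyses such
    rigs are used for. Provides a data model and CSV dialect for per-second
    beam-crossing counts and fly position, a protocol compiler that turns
    declarative light protocols (sudden-darkness pulse trains, light:dark
    cycles, zone-based feedback rules) into millisecond-resolution stimulus
    logs, a per-second feedback controller mapping fly position to zone
    illumination, and an agent-based one-dimensional locomotion simulator with
    startle, habituation, circadian modulation, food attraction and blue-light
    aversion. Analysis routines cover the startle delta index with dead-fly
    exclusion and responder classification, epoch-averaged habituation trends
    (one-way ANOVA with a post hoc linear-trend contrast), circadian
    two-choice food preference at the tube ends, and light-colour place
    preference under zone swaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
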