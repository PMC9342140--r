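Package: cvrmodel
Title: Cardiovascular Responses to Exercise Under Heat, Dehydration and
    Altitude Stress
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic algebraic model of whole-body cardiovascular
    responses at rest and during exercise. From an individual's age, mass,
    height, sex and maximal oxygen uptake it derives resting and maximal
    stroke volume, heart rate and cardiac output, then modulates these for
    hypobaric hypoxia (attenuated oxygen extraction), heat strain and
    dehydration (a cardiac heat strain index), partitions cardiac output
    into core, skin and muscle blood flows, and adjudicates aerobic task
    failure. Includes a time-series scenario simulator with CSV input and
    output, fixture generators for graded-exercise and fixed-load
    protocols, a predicted-versus-measured heart-rate regression harness,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
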