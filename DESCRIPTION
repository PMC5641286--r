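Package: hitec
Title: Interactive-Activation Simulation of Perception-Action Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a localist interactive-activation network in which
    perception and action planning share a common layer of feature codes
    (Theory of Event Coding). Implements shunting recurrent dynamics with
    voltage-dependent top-down feedback and winner-take-all lateral
    inhibition, Hebbian ideomotor (action-effect) learning via motor
    babbling, declarative internalization of task instructions as
    feature-task wiring, and seeded reproductions of five classic
    stimulus-response compatibility experiments (action-effect learning,
    response-effect compatibility, the auditory Simon task, the Stroop task,
    and the inverted Simon task). Reaction time is modelled as cycles from
    stimulus onset to a motor code crossing the response threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
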