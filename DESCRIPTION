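Package: esec
Title: Enriched Semantic Event Chains for Manipulation Action Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents tabletop manipulation actions as enriched Semantic Event
    Chains (eSEC): 30-row symbolic matrices recording touching, static and
    dynamic spatial relations between pairs of fundamental objects (hand,
    ground, up to three manipulated objects) at every relational change event.
    Provides geometric relation extraction from axis-aligned cube-scene
    trajectories, event compression into eSEC matrices, similarity-based
    progressive action classification with predictive-power scoring, Shannon
    self-information analysis of column codes with logistic observer-model
    fitting and BIC comparison, and a scripted simulator generating cube-scene
    trajectories for ten manipulation actions (chop, cut, hide, uncover, put on
    top, take down, lay, push, shake, stir).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
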