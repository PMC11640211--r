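Package: broilervent
Title: Heat-Balance Ventilation Control for Mechanically Ventilated Broiler Houses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a ventilation-rate-requirement (VRR) controller for
    tunnel-ventilated broiler houses based on a sensible/latent heat balance
    of the flock, the building envelope, and evaporative cooling pads,
    together with the conventional set-temperature stage controller, a
    lumped-parameter (single-zone) thermal simulator with a synthetic
    diurnal weather generator, and an audit engine for ventilation-rate and
    temperature discrepancy analysis and fan/pad energy accounting on
    operation logs. Closed-loop episodes allow the two control strategies to
    be compared without farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
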