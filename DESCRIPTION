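Package: reflexCRN
Title: Deterministic Simulation of a DNA Strand-Displacement Circuit with
    Classical Conditioning
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mass-action chemical reaction network (CRN) simulator for a
    DNA strand-displacement circuit that acquires, generalizes and forgets
    a Pavlovian conditioned reflex. Provides S4 containers for reaction
    networks, instantaneous dose schedules and trajectories; a stiff ODE
    driver with integrator restarts at dose events; builders for the
    two-input conditioned-reflex circuit, its n-input generalization and a
    photoswitchable seesaw threshold gate; experiment drivers for learning,
    forgetting, input-synchronization and truth-table studies; and a
    genetic-algorithm harness for parameter estimation with a local
    sensitivity utility.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    pracma,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
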