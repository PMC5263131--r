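Package: neuroloop
Title: Closed-Loop Spiking Neural Network and Robot Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained, desk-scale closed-loop neurorobotics simulator:
    a leaky integrate-and-fire spiking network simulator with stimulus
    and readout devices, a deterministic 2D robot and world simulator
    with a synthetic raycast camera, and a transfer-function framework that
    couples the two under a fixed-timestep synchronization engine with a
    simulation lifecycle state machine, parametrized reset, and timed
    environment events. Ships three end-to-end experiments: a Braitenberg
    vehicle that seeks red screens, motor-babbling forward-model learning on
    a planar arm, and retina-based visual tracking through a red-green
    opponency microcircuit chain feeding a two-layer spiking readout with
    centroid decoding. All monitor outputs are tidy tibbles exportable to CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
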