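Package: mecstrand
Title: Strain Modulation of Impulse Conduction in Cardiomyocyte Strands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for mechano-electric coupling
    experiments on patterned cardiomyocyte strands grown on dielectric
    elastomer actuators. Models the cubic voltage-strain law of the actuator
    with constant-strain-rate ramps and viscoelastic creep, simulates impulse
    propagation along a discrete resistive cell chain whose cytoplasmic axial
    resistance scales with strain, synthesises multielectrode extracellular
    electrograms (biphasic field potentials, AC coupling, quantisation, noise
    and stimulation artifacts), extracts local activation times by Gaussian
    fits to the electrogram derivative, and converts activation-time
    differences into conduction-velocity/strain laws, the cytoplasmic versus
    gap-junctional resistance partition, and strain-rate-independence
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
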