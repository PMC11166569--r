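Package: tensiopipe
Title: Membrane Tension and Mechanosensitive Channel Activation Analysis for
    Force-Controlled Micropipette Experiments
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolbox for single-cell mechanosensitivity experiments in
    which adherent cells are indented and aspirated with a force-controlled
    micropipette while channel activation is read out by calcium imaging and
    membrane tension by fluorescence-lifetime imaging of a tension-sensitive
    probe. Implements Boltzmann (sigmoid) fitting of cumulative
    activation-pressure histograms with a composite goodness-of-model error,
    the half-activation pressure versus indentation-force line, total
    activation pressure, conversion of stimuli to membrane tension via linear
    coefficients, time-correlated single-photon-counting (TCSPC) reconvolution
    lifetime fitting and lifetime imaging, lifetime-to-tension calibration,
    kymograph analysis, calcium wave-front speed estimation, Hertz-model cell
    stiffness extraction, and a coarse-grained membrane spring-network
    simulator of tension confinement by cytoskeletal anchors. Ships synthetic
    generators for every input type so the full pipeline is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
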