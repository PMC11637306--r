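Package: axonwave
Title: Compartmental Simulation and Analysis of Action Potentials in
    Varicose Axons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how axon caliber shapes the action potential
    (AP) in thin, varicose axons such as hippocampal mossy fibers. Provides a
    branched compartmental cable solver with Hodgkin-Huxley sodium and
    potassium currents, an optional size-compensating potassium conductance,
    and a Goldman-Hodgkin-Katz calcium channel mixture; AP waveform metrics
    (onset, area, half-width, level width, train broadening); per-bouton
    calcium influx and power-law release mapping; a local-capacitance probe
    based on multiexponential fitting of voltage-clamp transients; a forward
    model of pipette and amplifier distortion with conductance-fitting AP
    correction; a voltage-sensitive-dye imaging pipeline with photobleaching
    correction and spike-locked shift-and-mean temporal oversampling; and
    seeded generators for synthetic morphologies, recordings, and image
    stacks so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    signal,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
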