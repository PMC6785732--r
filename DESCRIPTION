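Package: permeon
Title: Ion Permeation Analysis for Potassium Channel Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing potassium ion permeation through
    inwardly rectifying K+ channel pores from molecular dynamics
    trajectories. Detects committed permeation events at the helix-bundle
    crossing, G-loop and selectivity-filter levels, computes
    effective-biased potentials of mean force by Boltzmann inversion of
    ion occupancy, quantifies gate geometry (minimum inter-subunit
    distances, Calpha distances, dihedrals, cytoplasmic-domain rotation,
    cation-pi geometry), pore wetting and ion hydration, hydrogen bonds,
    and classifies the selectivity-filter conduction mechanism (direct
    versus water-mediated knock-on). Includes a Brownian-dynamics
    synthetic pore generator with known ground truth so every analysis
    stage can be validated without microsecond-scale simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
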