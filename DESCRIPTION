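Package: radcell
Title: Stochastic Multicellular Simulation of X-Ray DNA Damage, Free-End
    Misrejoining and Cell Death
Version: 0.1.0
Authors@R:
    person("radcell", "developers", email = "radcell@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo simulation of radiation response in a voxelized
    multicellular tumor. Builds randomized non-overlapping ellipsoidal cells
    with concentric nuclei on a 2 micron voxel lattice, generates surrogate
    low-LET electron track events (direct energy depositions and hydroxyl
    radical interaction positions) for a prescribed dose, converts the events
    into DNA double-strand breaks with oxygen-dependent strand-break
    probabilities and spatial clustering into 10 base-pair segments, simulates
    proximity-based misrejoining of complex double-strand break free-ends, and
    computes linear-quadratic dose responses, oxygen enhancement ratios, D10
    and SF2. Includes a vascular oxygenation model for millimetre-scale tumors
    (connected vessel network, distance-based pO2, necrosis) and pipelines for
    sensitivity analyses, direct-effect ablations and whole-tumor experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
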