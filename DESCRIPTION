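Package: poreflux
Title: Ion Permeation, Conductance and Pore Analysis for Channel Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for ion-channel permeation studies:
    detection of complete ion traversals and their entry pathways, dwell-time
    statistics, conductance estimation under an applied transmembrane voltage
    with segment-based uncertainty, transmembrane voltage from applied fields
    or charge-density profiles (Poisson double integration), volume-normalized
    1D/2D ion occupancy maps and binding-site occupancy, first-hydration-shell
    composition profiles, largest-inscribed-sphere pore-radius profiles with
    gate metrics and block-averaged correlations, and the accompanying
    statistics (unpaired Student's t tests, kernel density estimates).
    Includes an overdamped-Langevin synthetic trajectory generator with a
    ground-truth event log so every analysis stage can be validated at desk
    scale without molecular-dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
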