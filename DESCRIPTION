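Package: hbondnet
Title: Hydrogen-Bond Speciation, Networks and Transport from Molecular
    Dynamics Trajectories of Ether Alcohols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric hydrogen-bond detection and speciation (intermolecular
    hydroxyl-hydroxyl, intermolecular hydroxyl-ether, intramolecular
    hydroxyl-ether) for coordinate trajectories of n-octanol-like ether
    alcohols, with per-frame bond-network statistics (components, cycles,
    double-hydrogen-bonded dimers), bond-persistence analysis via windowed
    bonded-time histograms, complementary cumulative distributions and
    single-exponential decay fits, radial distribution functions under
    periodic boundaries (including the intramolecular component obtained by
    subtraction), and transport-property extraction: self-diffusion from mean
    squared displacements with the Yeh-Hummer finite-size correction,
    Green-Kubo shear viscosity from pressure-tensor fluctuations,
    Stokes-Einstein products and two-point Arrhenius activation energies.
    Includes synthetic-trajectory generators (planted hydrogen-bond motifs,
    Brownian particles, ideal gas, exponential bond lifetimes,
    Ornstein-Uhlenbeck stress series) with exact ground truth so that every
    analysis stage is testable without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
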