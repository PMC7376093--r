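Package: lipidkin
Title: Lipid-Protein Contact Kinetics and Domain Dynamics from Membrane Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of protein-lipid interactions and domain dynamics in
    membrane molecular dynamics trajectories. Implements dual-cutoff
    (hysteresis) lipid contact detection, contact-duration survival curves
    with bi-exponential fitting to estimate dissociation rates (k_off) and
    residence times, per-residue interaction profiles, binding-site occupancy
    time series, lateral radial distribution functions around a transmembrane
    domain, inter-domain plane angles, domain RMSD after reference
    superposition, and principal component analysis of domain motions.
    Includes a synthetic-trajectory generator with Markovian site binding and
    prescribed hinge motion so every analysis stage is testable against known
    ground truth, plus readers and writers for GRO, PDB and DCD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
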