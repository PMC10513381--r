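Package: slabsim
Title: Residue-Level Coarse-Grained Simulation and Analysis of
    Biomolecular Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds one-bead-per-residue models of intrinsically
    disordered proteins and one-bead-per-nucleotide double-stranded DNA,
    assigns hydropathy-scale (HPS, with KR or Urry scales), Wang-Frenkel
    (Mpipi-style), contact-matrix (MOFF-style) and MRG-CG DNA force
    fields with Debye-Hueckel implicit-ion electrostatics, and runs
    reference molecular dynamics: Langevin (BAOAB) and Nose-Hoover
    thermostats, Monte Carlo barostat NPT compression, temperature
    annealing and temperature replica exchange.  Includes condensate
    analyses: radius of gyration, contact-network clustering, slab
    density profiles, coexistence densities, critical-temperature
    fitting with the 3D-Ising exponent, and polymer persistence length.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
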