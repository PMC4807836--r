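Package: vibrolf
Title: Vibrationally-Assisted Olfaction Analysis: Electron-Phonon Coupling of an Odorant in a Receptor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probing the vibrational theory of olfaction on an
    odorant bound in a receptor model. Computes harmonic normal modes from
    Cartesian Hessians with Eckart projection, IR intensities and broadened
    spectra, local electric fields from distributed-multipole (optionally
    polarizable) embedding potentials, per-mode electron-phonon couplings and
    Huang-Rhys factors for a donor-to-acceptor electron transfer, Marcus-theory
    rates and reorganization-energy estimates from two-state potential-energy
    sampling, and trajectory binding metrics (RMSD, coordination distances,
    nonbonded interaction energies). Includes synthetic-data generators with
    closed-form ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
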