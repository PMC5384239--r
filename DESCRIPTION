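Package: flycast
Title: Staged Restrained Dynamics and Fly-Casting Analysis for
    Protein-Protein Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses the staged binding of a disordered or
    partially disordered protein to a structured partner. Provides a
    one-bead-per-residue Go-type model with an overdamped Langevin
    integrator, centre-of-mass distance restraints (two-sided harmonics
    and one-sided walls) arranged into a three-region protocol
    (pseudo-native capture, free exploration, native-complex formation),
    and the accompanying analysis suite: Kabsch superposition RMSD and
    RMSF, per-segment RMSD, Shrake-Rupley solvent-accessible surface
    area and normalised complex SASA, polar-contact counting, and the
    capture radius (radius of gyration of a residue selection) used to
    characterise fly-casting. Synthetic generators provide toy dimers,
    jitter trajectories and breathing helices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
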