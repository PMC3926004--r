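Package: bfaudit
Title: Audit of B-Factor Fidelity Under Conformational Averaging in
    Protein Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Synthetic crystal ensembles with known, controllable
    conformational heterogeneity (harmonic, two-site and rotamer-flip
    disorder), crystallographic structure-factor calculation with vector
    averaging over snapshots, reduction of P1 supercell data to C222(1),
    a simplified least-squares isotropic/anisotropic B-factor refinement
    engine, and comparison tools quantifying how far refined displacement
    parameters deviate from the true atomic fluctuations known from the
    ensemble.  Implements the full generate -> structure factors ->
    average -> reduce -> refine -> compare pipeline with reproducible
    seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
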