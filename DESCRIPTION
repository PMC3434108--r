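Package: triadcore
Title: Structural Comparison of Chymotrypsin-Like Serine Protease Cores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative structural analysis of PA-clan (S1 family,
    trypsin-fold) serine proteases: rigid-body Kabsch superposition with
    iterative common-core detection, catalytic His/Asp/Ser triad Calpha
    geometry and cross-structure statistics, alignment conservation occupancy
    under chymotrypsin reference numbering, physico-chemical amino-acid
    composition profiling, geometry-based model validation (Ramachandran
    phi/psi summaries, all-atom clashscore, bond length/angle RMSD against
    standard values), dihedral-window secondary-structure assignment,
    Shrake-Rupley solvent-accessible surface area with a qualitative Coulomb
    surface-potential classifier, and seeded synthetic structure/alignment
    generators so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
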