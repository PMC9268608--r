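Package: stereoscreen
Title: Stereoisomer Target Prioritisation from Docking Scores and
    Trajectory Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for prioritising protein targets of stereoisomeric
    ligands from virtual-screening output. Implements a two-criterion
    target-selection gate (docking energy versus a known inhibitor, and
    binding-site similarity as interacting-residue overlap), a
    rank-and-weight consensus scoring system over protein groups
    (4-3-2-1 competition ranks multiplied by 3-2-1 subcellular
    accessibility weights), per-protein isomer-score variability
    statistics, and molecular-dynamics trajectory statistics (RMSD,
    per-residue C-alpha RMSF, ligand-protein centre-of-mass distance,
    and per-residue bound-versus-free distance shifts with a 2 Angstrom
    significance rule). A synthetic-data generator plants known
    isomer-preference structure and conformational shifts so that every
    pipeline stage can be tested without docking or MD engines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
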