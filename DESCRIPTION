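Package: mnapred
Title: Protein Secondary-Structure Prediction from Atom-Centred MNA Descriptors
Version: 0.1.0
Authors@R:
    person("mnapred", "developers", email = "mnapred@example.org", role = c("aut", "cre"))
Description: Predicts the eight DSSP secondary-structure states of protein
    fragments from their structural formulae. Peptide sequences are converted
    to explicit-hydrogen molecular graphs, described by canonical multilevel
    neighbourhoods of atoms (MNA) descriptor strings, and classified by a
    naive-Bayes-style one-vs-rest model with empirical Pa/Pi outputs,
    leave-one-out AUC validation, sliding-window whole-protein annotation and
    Q3/Q8 scoring. Includes a DSSP-output parser and segment filters for
    dataset assembly, MOL V3000 SDF input/output, a seeded synthetic peptide
    generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
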