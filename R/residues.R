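# Amino-acid residue templates used to build peptide structural formulae.
#
# Each template lists the side-chain heavy atoms in PDB naming order, the
# number of explicit hydrogens each carries, and the side-chain bonds with
# their orders (Kekule forms for aromatic rings). The backbone (N, CA, C, O
# and the C-terminal hydroxyl OXT) is shared and instantiated by
# build_peptide_graph(). Neutral protonation throughout: NH2/COOH termini,
# COOH side chains for Asp/Glu, NH2 for Lys, neutral guanidine for Arg, and
# the N-epsilon-H tautomer for His.

# side-chain atom: name, element, number of attached hydrogens
.sc <- function(name, element, nh) list(name = name, element = element, nh = nh)
# bond between named atoms ("CA" and "N" refer to the backbone)
.bd <- function(a, b, order = 1L) list(a = a, b = b, order = as.integer(order))

.residue_templates <- list(
  A = list(atoms = list(.sc("CB", "C", 3L)),
           bonds = list(.bd("CA", "CB"))),
  R = list(atoms = list(.sc("CB", "C", 2L), .sc("CG", "C", 2L), .sc("CD", "C", 2L),
                        .sc("NE", "N", 1L), .sc("CZ", "C", 0L), .sc("NH1", "N", 1L),
                        .sc("NH2", "N", 2L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "CD"),
                        .bd("CD", "NE"), .bd("NE", "CZ"), .bd("CZ", "NH1", 2L),
                        .bd("CZ", "NH2"))),
  N = list(atoms = list(.sc("CB", "C", 2L), .sc("CG", "C", 0L), .sc("OD1", "O", 0L),
                        .sc("ND2", "N", 2L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "OD1", 2L),
                        .bd("CG", "ND2"))),
  D = list(atoms = list(.sc("CB", "C", 2L), .sc("CG", "C", 0L), .sc("OD1", "O", 0L),
                        .sc("OD2", "O", 1L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "OD1", 2L),
                        .bd("CG", "OD2"))),
  C = list(atoms = list(.sc("CB", "C", 2L), .sc("SG", "S", 1L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "SG"))),
  Q = list(atoms = list(.sc("CB", "C", 2L), .sc("CG", "C", 2L), .sc("CD", "C", 0L),
                        .sc("OE1", "O", 0L), .sc("NE2", "N", 2L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "CD"),
                        .bd("CD", "OE1", 2L), .bd("CD", "NE2"))),
  E = list(atoms = list(.sc("CB", "C", 2L), .sc("CG", "C", 2L), .sc("CD", "C", 0L),
                        .sc("OE1", "O", 0L), .sc("OE2", "O", 1L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "CD"),
                        .bd("CD", "OE1", 2L), .bd("CD", "OE2"))),
  G = list(atoms = list(), bonds = list()),
  H = list(atoms = list(.sc("CB", "C", 2L), .sc("CG", "C", 0L), .sc("ND1", "N", 0L),
                        .sc("CD2", "C", 1L), .sc("CE1", "C", 1L), .sc("NE2", "N", 1L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "ND1"),
                        .bd("CG", "CD2", 2L), .bd("ND1", "CE1", 2L),
                        .bd("CE1", "NE2"), .bd("NE2", "CD2"))),
  I = list(atoms = list(.sc("CB", "C", 1L), .sc("CG1", "C", 2L), .sc("CG2", "C", 3L),
                        .sc("CD1", "C", 3L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "CG1"), .bd("CB", "CG2"),
                        .bd("CG1", "CD1"))),
  L = list(atoms = list(.sc("CB", "C", 2L), .sc("CG", "C", 1L), .sc("CD1", "C", 3L),
                        .sc("CD2", "C", 3L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "CD1"),
                        .bd("CG", "CD2"))),
  K = list(atoms = list(.sc("CB", "C", 2L), .sc("CG", "C", 2L), .sc("CD", "C", 2L),
                        .sc("CE", "C", 2L), .sc("NZ", "N", 2L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "CD"),
                        .bd("CD", "CE"), .bd("CE", "NZ"))),
  M = list(atoms = list(.sc("CB", "C", 2L), .sc("CG", "C", 2L), .sc("SD", "S", 0L),
                        .sc("CE", "C", 3L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "SD"),
                        .bd("SD", "CE"))),
  F = list(atoms = list(.sc("CB", "C", 2L), .sc("CG", "C", 0L), .sc("CD1", "C", 1L),
                        .sc("CD2", "C", 1L), .sc("CE1", "C", 1L), .sc("CE2", "C", 1L),
                        .sc("CZ", "C", 1L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "CD1", 2L),
                        .bd("CD1", "CE1"), .bd("CE1", "CZ", 2L), .bd("CZ", "CE2"),
                        .bd("CE2", "CD2", 2L), .bd("CD2", "CG"))),
  P = list(atoms = list(.sc("CB", "C", 2L), .sc("CG", "C", 2L), .sc("CD", "C", 2L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "CD"),
                        .bd("CD", "N"))),
  S = list(atoms = list(.sc("CB", "C", 2L), .sc("OG", "O", 1L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "OG"))),
  T = list(atoms = list(.sc("CB", "C", 1L), .sc("OG1", "O", 1L), .sc("CG2", "C", 3L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "OG1"), .bd("CB", "CG2"))),
  W = list(atoms = list(.sc("CB", "C", 2L), .sc("CG", "C", 0L), .sc("CD1", "C", 1L),
                        .sc("CD2", "C", 0L), .sc("NE1", "N", 1L), .sc("CE2", "C", 0L),
                        .sc("CE3", "C", 1L), .sc("CZ2", "C", 1L), .sc("CZ3", "C", 1L),
                        .sc("CH2", "C", 1L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "CD1", 2L),
                        .bd("CD1", "NE1"), .bd("NE1", "CE2"), .bd("CE2", "CD2"),
                        .bd("CD2", "CG"), .bd("CE2", "CZ2", 2L), .bd("CZ2", "CH2"),
                        .bd("CH2", "CZ3", 2L), .bd("CZ3", "CE3"),
                        .bd("CE3", "CD2", 2L))),
  Y = list(atoms = list(.sc("CB", "C", 2L), .sc("CG", "C", 0L), .sc("CD1", "C", 1L),
                        .sc("CD2", "C", 1L), .sc("CE1", "C", 1L), .sc("CE2", "C", 1L),
                        .sc("CZ", "C", 0L), .sc("OH", "O", 1L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "CG"), .bd("CG", "CD1", 2L),
                        .bd("CD1", "CE1"), .bd("CE1", "CZ", 2L), .bd("CZ", "CE2"),
                        .bd("CE2", "CD2", 2L), .bd("CD2", "CG"), .bd("CZ", "OH"))),
  V = list(atoms = list(.sc("CB", "C", 1L), .sc("CG1", "C", 3L), .sc("CG2", "C", 3L)),
           bonds = list(.bd("CA", "CB"), .bd("CB", "CG1"), .bd("CB", "CG2")))
)

#' Standard amino-acid one-letter codes supported by the peptide builder
#' @return Character vector of the 20 standard one-letter codes.
#' @export
amino_acid_codes <- function() names(.residue_templates)
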