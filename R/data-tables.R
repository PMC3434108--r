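# Bundled reference tables.  Each is exposed through a small accessor so the
# defaults are documented in one place and every consumer can be handed an
# override.

## Strict 3-letter -> 1-letter table for the 20 standard amino acids.
## Anything else (MSE, ligands, ...) translates to "X".
.AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

.AA1 <- stats::setNames(names(.AA3), unname(.AA3))

aa_three_to_one <- function(res_names) {
  out <- unname(.AA3[toupper(res_names)])
  out[is.na(out)] <- "X"
  out
}

#' Van der Waals radii used by the clashscore
#'
#' Heavy-atom van der Waals radii in angstroms, keyed by element symbol
#' (C 1.70, N 1.55, O 1.52, S 1.80).  Hydrogens are absent from most X-ray
#' depositions, so the clashscore here is a heavy-atom score; absolute values
#' are therefore not comparable with tools that add hydrogens first.
#'
#' @return Named numeric vector of radii (angstrom).
#' @export
vdwRadii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
}

## Covalent radii (angstrom) used only to infer the bond graph when excluding
## covalently connected pairs from clash counting and contact detection.
covalentRadii <- function() {
  c(C = 0.77, N = 0.70, O = 0.66, S = 1.04, H = 0.37)
}

#' Standard peptide bond lengths and angles
#'
#' Reference backbone geometry in the Engh--Huber convention, used both by the
#' bond-geometry validation metric and by the ideal-geometry synthetic
#' builders (so fixtures built from this table validate to an RMSD of zero).
#' Atom names prefixed with "+" belong to the following residue.
#'
#' @return A list with two data frames: `bonds` (atom1, atom2, length in
#'   angstrom) and `angles` (atom1, atom2, atom3, angle in degrees).
#' @export
standardGeometry <- function() {
  list(
    bonds = data.frame(
      atom1 = c("N", "CA", "C", "C", "CA"),
      atom2 = c("CA", "C", "O", "+N", "CB"),
      length = c(1.458, 1.525, 1.231, 1.329, 1.530),
      stringsAsFactors = FALSE
    ),
    angles = data.frame(
      atom1 = c("N", "CA", "CA", "O", "C"),
      atom2 = c("CA", "C", "C", "C", "+N"),
      atom3 = c("C", "O", "+N", "+N", "+CA"),
      angle = c(111.2, 120.8, 116.2, 123.0, 121.7),
      stringsAsFactors = FALSE
    )
  )
}

#' Residue conservation groups
#'
#' The strong and weak residue groups used to assign ":" and "." conservation
#' symbols to alignment columns, following the convention of the classic
#' progressive aligner output.  Override by passing your own list of character
#' vectors to [columnConservation()].
#'
#' @return List with elements `strong` and `weak`, each a character vector of
#'   residue-group strings.
#' @export
conservationGroups <- function() {
  list(
    strong = c("STA", "NEQK", "NHQK", "NDEQ", "QHRK",
               "MILV", "MILF", "HY", "FYW"),
    weak = c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND",
             "SNDEQK", "NDEQHK", "NEQHRK", "FVLIM", "HFY")
  )
}

#' Physico-chemical amino-acid classes
#'
#' Class memberships for molar-percentage composition profiling, following the
#' EMBOSS convention.  `polar` is defined as the complement of `nonpolar` over
#' the 20 standard residues so that the two always sum to 100 percent.
#' Classes overlap, so no overall sum constraint exists.
#'
#' @return Named list of character vectors (one-letter residue codes).
#' @export
compositionClasses <- function() {
  nonpolar <- c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W", "Y")
  list(
    tiny = c("A", "C", "G", "S", "T"),
    small = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
    aliphatic = c("A", "I", "L", "V"),
    aromatic = c("F", "H", "W", "Y"),
    nonpolar = nonpolar,
    polar = setdiff(unname(.AA3), nonpolar),
    charged = c("D", "E", "H", "K", "R"),
    basic = c("H", "K", "R"),
    acidic = c("D", "E")
  )
}

## Hydrogen-bond donor heavy atoms with the antecedent atom used for the
## donor-antecedent-donor-acceptor angle, and acceptor atoms.  "*" matches any
## residue type.
hbond_donors <- function() {
  data.frame(
    resid = c("*", "SER", "THR", "TYR", "LYS", "ARG", "ARG", "ARG",
              "HIS", "HIS", "ASN", "GLN", "TRP"),
    atom = c("N", "OG", "OG1", "OH", "NZ", "NE", "NH1", "NH2",
             "ND1", "NE2", "ND2", "NE2", "NE1"),
    antecedent = c("CA", "CB", "CB", "CZ", "CE", "CD", "CZ", "CZ",
                   "CG", "CE1", "CG", "CD", "CE2"),
    stringsAsFactors = FALSE
  )
}

hbond_acceptors <- function() {
  data.frame(
    resid = c("*", "*", "ASP", "ASP", "GLU", "GLU", "SER", "THR",
              "TYR", "ASN", "GLN", "HIS", "HIS"),
    atom = c("O", "OXT", "OD1", "OD2", "OE1", "OE2", "OG", "OG1",
             "OH", "OD1", "OE1", "ND1", "NE2"),
    stringsAsFactors = FALSE
  )
}
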