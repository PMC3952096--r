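#' @keywords internal
"_PACKAGE"

## Element parameters used by the interaction detectors.
## Covalent radii follow the classic Pauling/CCDC single-bond values used by
## the FIRST/KINARI lineage of rigidity tools; van der Waals radii are Bondi's.

.covalent_radius <- c(
  H = 0.37, D = 0.37, C = 0.77, N = 0.75, O = 0.73, S = 1.02, P = 1.06,
  SE = 1.17, F = 0.71, CL = 0.99, BR = 1.14, I = 1.33, B = 0.82
)

.vdw_radius <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, B = 1.92
)

.backbone_names <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA",
                     "HA2", "HA3", "HXT")

.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

## Hydrophobicity classes used for reporting (Kyte-Doolittle-like coarse bins).
.hydrophobicity_very <- c("VAL", "ILE", "LEU", "PHE", "MET", "TRP", "CYS")
.hydrophobicity_slight <- c("ALA", "GLY", "TYR")

## Intra-residue bonds that are locked (non-rotatable): aromatic / planar ring
## bonds, sp2 carbonyl, carboxylate, amide and guanidinium bonds. A locked bond
## removes all six relative degrees of freedom between the two incident bodies.
.locked_bond_templates <- list(
  ALL = list(c("C", "O"), c("C", "OXT")),
  PHE = list(c("CG", "CD1"), c("CD1", "CE1"), c("CE1", "CZ"),
             c("CZ", "CE2"), c("CE2", "CD2"), c("CD2", "CG")),
  TYR = list(c("CG", "CD1"), c("CD1", "CE1"), c("CE1", "CZ"),
             c("CZ", "CE2"), c("CE2", "CD2"), c("CD2", "CG")),
  TRP = list(c("CG", "CD1"), c("CD1", "NE1"), c("NE1", "CE2"),
             c("CE2", "CD2"), c("CD2", "CG"), c("CE2", "CZ2"),
             c("CZ2", "CH2"), c("CH2", "CZ3"), c("CZ3", "CE3"),
             c("CE3", "CD2")),
  HIS = list(c("CG", "ND1"), c("ND1", "CE1"), c("CE1", "NE2"),
             c("NE2", "CD2"), c("CD2", "CG")),
  PRO = list(c("N", "CA"), c("CA", "CB"), c("CB", "CG"),
             c("CG", "CD"), c("CD", "N")),
  ARG = list(c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2")),
  ASP = list(c("CG", "OD1"), c("CG", "OD2")),
  GLU = list(c("CD", "OE1"), c("CD", "OE2")),
  ASN = list(c("CG", "OD1"), c("CG", "ND2")),
  GLN = list(c("CD", "OE1"), c("CD", "NE2"))
)

## Hydrogen-bond donor / acceptor heavy atoms by residue type. Backbone N is a
## donor (except proline) and backbone O / OXT acceptors for every residue.
.hbond_donor_sidechain <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = c("ND2"), GLN = c("NE2"),
  HIS = c("ND1", "NE2"), LYS = c("NZ"), SER = c("OG"), THR = c("OG1"),
  TRP = c("NE1"), TYR = c("OH"), CYS = c("SG")
)

.hbond_acceptor_sidechain <- list(
  ASN = c("OD1"), ASP = c("OD1", "OD2"), GLN = c("OE1"),
  GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"), SER = c("OG"),
  THR = c("OG1"), TYR = c("OH"), MET = c("SD"), CYS = c("SG")
)

#' Coarse hydrophobicity class of a residue type
#'
#' Bins the twenty standard amino acids into `"very"` hydrophobic (Val, Ile,
#' Leu, Phe, Met, Trp, Cys), `"slight"` (Ala, Gly, Tyr) and `"none"` for the
#' polar and charged residues. Used in the reporting tables.
#'
#' @param aa Character vector of 3-letter residue codes (case-insensitive).
#' @return Character vector with values `"very"`, `"slight"` or `"none"`.
#' @export
#' @examples
#' hydrophobicity_class(c("LEU", "ALA", "SER"))
hydrophobicity_class <- function(aa) {
  aa <- toupper(aa)
  dplyr::case_when(
    aa %in% .hydrophobicity_very ~ "very",
    aa %in% .hydrophobicity_slight ~ "slight",
    TRUE ~ "none"
  )
}

## One- <-> three-letter residue code maps.
.aa1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

covalent_radius <- function(element) {
  r <- .covalent_radius[toupper(element)]
  if (anyNA(r)) {
    bad <- unique(toupper(element)[is.na(r)])
    stop("no covalent radius defined for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(r)
}

vdw_radius <- function(element) {
  r <- .vdw_radius[toupper(element)]
  if (anyNA(r)) {
    bad <- unique(toupper(element)[is.na(r)])
    stop("no van der Waals radius defined for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(r)
}
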