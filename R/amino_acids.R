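# Amino-acid metadata: canonical chi counts, chi-defining atom quadruples,
# side-chain hydrogen-bond donors/acceptors. Three-letter codes throughout.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Number of canonical chi dihedral angles for an amino acid
#' @param aa three-letter code (vectorized)
#' @return integer count, 0 for ALA/GLY up to 4 for ARG/LYS
#' @export
n_chi <- function(aa) {
  counts <- c(ALA = 0L, GLY = 0L,
              SER = 1L, CYS = 1L, THR = 1L, VAL = 1L,
              ILE = 2L, LEU = 2L, PRO = 2L, ASP = 2L, ASN = 2L,
              HIS = 2L, PHE = 2L, TYR = 2L, TRP = 2L,
              MET = 3L, GLU = 3L, GLN = 3L,
              ARG = 4L, LYS = 4L)
  out <- counts[toupper(aa)]
  if (any(is.na(out))) {
    stop("unknown amino acid code: ",
         paste(unique(aa[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

# chi_k is the torsion of the quadruple chi_atoms[[aa]][[k]]
chi_atoms <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  CYS = list(c("N", "CA", "CB", "SG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ"))
)

# side-chain hydrogen-bond donors (heavy atom + antecedent) and acceptors
hbond_donors <- list(
  SER = list(c("OG", "CB")), THR = list(c("OG1", "CB")),
  TYR = list(c("OH", "CZ")), CYS = list(c("SG", "CB")),
  ASN = list(c("ND2", "CG")), GLN = list(c("NE2", "CD")),
  HIS = list(c("ND1", "CG"), c("NE2", "CE1")),
  LYS = list(c("NZ", "CE")), TRP = list(c("NE1", "CD1")),
  ARG = list(c("NE", "CD"), c("NH1", "CZ"), c("NH2", "CZ"))
)
hbond_acceptors <- list(
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), MET = "SD"
)

#' Chemical element of a PDB heavy-atom name
#' @param name PDB atom name(s), e.g. "CA", "OD1", "SG", "NZ"
#' @return element symbol(s): "C", "N", "O" or "S"
#' @keywords internal
atom_element <- function(name) {
  substr(gsub("^[0-9 ]+", "", name), 1, 1)
}

.geom_env <- new.env(parent = emptyenv())

# Side-chain internal-coordinate table, loaded once per session.
sidechain_geometry <- function() {
  if (is.null(.geom_env$tab)) {
    path <- system.file("extdata", "sidechain_geometry.tsv",
                        package = "rotamrf", mustWork = TRUE)
    .geom_env$tab <- utils::read.table(path, header = TRUE, sep = "\t",
                                       comment.char = "#",
                                       stringsAsFactors = FALSE)
  }
  .geom_env$tab
}

# Rows of the geometry table for one residue type, CB first.
sidechain_rows <- function(aa) {
  aa <- toupper(aa)
  if (!aa %in% AA3) stop("unknown amino acid code: ", aa)
  if (aa == "GLY") return(NULL)
  tab <- sidechain_geometry()
  rbind(tab[tab$aa == "ALL", , drop = FALSE],
        tab[tab$aa == aa, , drop = FALSE])
}
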