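# Residue chemistry tables: standard heavy-atom layouts, polar donor/acceptor
# atoms (N/O only; the contact criterion is distance-only, so sulfur is not
# treated as a hydrogen-bonding heavy atom), and charged side-chain sets used
# for salt-bridge enumeration.

#' Standard heavy-atom names for the 20 amino acids
#'
#' Returns the PDB heavy-atom names of one residue type, backbone first.
#' Used by the synthetic trajectory generator and by side-chain atom scoping.
#'
#' @param resname Three-letter residue code (case-insensitive).
#' @return Character vector of atom names.
#' @export
residue_atoms <- function(resname) {
  resname <- toupper(resname)
  tpl <- .residue_templates[[resname]]
  if (is.null(tpl)) stop("unknown residue code: ", resname)
  tpl
}

.residue_templates <- list(
  ALA = c("N", "CA", "C", "O", "CB"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  CYS = c("N", "CA", "C", "O", "CB", "SG"),
  GLN = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
  GLY = c("N", "CA", "C", "O"),
  HIS = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
  LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  MET = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("N", "CA", "C", "O", "CB", "CG", "CD"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  THR = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
  TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2",
          "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
          "CZ", "OH"),
  VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2")
)

# side-chain polar heavy atoms (N/O): list(donor = ..., acceptor = ...)
.sidechain_polar <- list(
  SER = list(donor = "OG",  acceptor = "OG"),
  THR = list(donor = "OG1", acceptor = "OG1"),
  TYR = list(donor = "OH",  acceptor = "OH"),
  ASN = list(donor = "ND2", acceptor = "OD1"),
  GLN = list(donor = "NE2", acceptor = "OE1"),
  ASP = list(donor = character(0), acceptor = c("OD1", "OD2")),
  GLU = list(donor = character(0), acceptor = c("OE1", "OE2")),
  LYS = list(donor = "NZ",  acceptor = character(0)),
  ARG = list(donor = c("NE", "NH1", "NH2"), acceptor = character(0)),
  HIS = list(donor = c("ND1", "NE2"), acceptor = c("ND1", "NE2")),
  TRP = list(donor = "NE1", acceptor = character(0))
)

# salt-bridge atom sets; His excluded by default (never invoked for the
# carrier's matrix-side salt bridges)
.saltbridge_basic  <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
.saltbridge_acidic <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Side-chain polar atoms of a residue
#'
#' @param resname Three-letter code.
#' @param role `"donor"`, `"acceptor"` or `"any"`.
#' @return Character vector of atom names (possibly empty).
#' @export
sidechain_polar_atoms <- function(resname, role = c("any", "donor", "acceptor")) {
  role <- match.arg(role)
  p <- .sidechain_polar[[toupper(resname)]]
  if (is.null(p)) return(character(0))
  switch(role,
    donor    = p$donor,
    acceptor = p$acceptor,
    any      = unique(c(p$donor, p$acceptor)))
}

.element_of <- function(atom_name) {
  # first non-digit character of the PDB atom name
  substr(gsub("^[0-9]+", "", atom_name), 1L, 1L)
}

.AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")
.AA3 <- stats::setNames(names(.AA1), unname(.AA1))

.aa_one <- function(res) {
  res <- toupper(res)
  if (nchar(res) == 1L) {
    if (!res %in% .AA1) stop("unknown residue code: ", res)
    return(res)
  }
  out <- unname(.AA1[res])
  if (is.na(out)) stop("unknown residue code: ", res)
  out
}

.aa_three <- function(res) {
  res <- toupper(res)
  if (nchar(res) == 3L) {
    if (!res %in% names(.AA1)) stop("unknown residue code: ", res)
    return(res)
  }
  out <- unname(.AA3[res])
  if (is.na(out)) stop("unknown residue code: ", res)
  out
}

# round half away from zero, as occupancy tables are conventionally printed
.round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
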