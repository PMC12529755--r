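# Residue chemistry tables used by the interaction classifiers. Atom names
# follow PDB v3 nomenclature; histidine protonation variants follow the
# common MD force-field conventions (HSD/HID delta-protonated, HSE/HIE
# epsilon-protonated, HSP/HIP doubly protonated and hence basic).

HIS_NAMES <- c("HIS", "HSD", "HSE", "HSP", "HID", "HIE", "HIP")
HIS_PROTONATED <- c("HSP", "HIP")

#' Residue chemistry table
#'
#' Per-residue atom-name sets driving the interaction classifiers: basic
#' side-chain nitrogens, acidic side-chain oxygens, side-chain carbons,
#' hydrogen-bond donors (heavy atom plus candidate hydrogen names) and
#' acceptors, a mutually exclusive physicochemical category, and the
#' anchor atoms used by the hydrophobic-versus-charged/polar repulsion
#' rule. Backbone amide N (donor) and carbonyl O (acceptor) are included
#' for every residue; terminal atoms (N-terminal N as charged, OXT) are
#' excluded from the charged sets by default.
#'
#' @param include_termini also count backbone N / OXT as charged-group
#'   atoms (off by default).
#' @return named list keyed by residue name, class `cc_chemistry`.
#' @export
residue_chemistry <- function(include_termini = FALSE) {
  sidechain_carbons <- list(
    ALA = "CB",
    ARG = c("CB", "CG", "CD", "CZ"),
    ASN = c("CB", "CG"),
    ASP = c("CB", "CG"),
    CYS = "CB",
    GLN = c("CB", "CG", "CD"),
    GLU = c("CB", "CG", "CD"),
    GLY = character(0),
    HIS = c("CB", "CG", "CD2", "CE1"),
    ILE = c("CB", "CG1", "CG2", "CD1", "CD"),
    LEU = c("CB", "CG", "CD1", "CD2"),
    LYS = c("CB", "CG", "CD", "CE"),
    MET = c("CB", "CG", "CE"),
    PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    PRO = c("CB", "CG", "CD"),
    SER = "CB",
    THR = c("CB", "CG2"),
    TRP = c("CB", "CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    VAL = c("CB", "CG1", "CG2"))

  basic_nitrogens <- list(
    LYS = "NZ",
    ARG = c("NE", "NH1", "NH2"))
  for (h in HIS_PROTONATED) basic_nitrogens[[h]] <- c("ND1", "NE2")

  acidic_oxygens <- list(
    ASP = c("OD1", "OD2"),
    GLU = c("OE1", "OE2"))

  # side-chain donors: heavy atom -> candidate attached hydrogen names
  donors <- list(
    SER = list(OG = c("HG", "HG1")),
    THR = list(OG1 = "HG1"),
    TYR = list(OH = "HH"),
    CYS = list(SG = c("HG", "HG1")),
    LYS = list(NZ = c("HZ1", "HZ2", "HZ3")),
    ARG = list(NE = "HE", NH1 = c("HH11", "HH12"), NH2 = c("HH21", "HH22")),
    ASN = list(ND2 = c("HD21", "HD22")),
    GLN = list(NE2 = c("HE21", "HE22")),
    TRP = list(NE1 = "HE1"))
  for (h in c("HIS", "HSD", "HID")) donors[[h]] <- list(ND1 = "HD1")
  for (h in c("HSE", "HIE")) donors[[h]] <- list(NE2 = "HE2")
  for (h in HIS_PROTONATED) donors[[h]] <- list(ND1 = "HD1", NE2 = "HE2")

  acceptors <- list(
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
    ASN = "OD1", GLN = "OE1",
    SER = "OG", THR = "OG1", TYR = "OH",
    MET = "SD", CYS = "SG")
  for (h in c("HIS", "HSD", "HID")) acceptors[[h]] <- "NE2"
  for (h in c("HSE", "HIE")) acceptors[[h]] <- "ND1"

  category <- c(
    LYS = "basic", ARG = "basic",
    ASP = "acidic", GLU = "acidic",
    SER = "polar", THR = "polar", ASN = "polar", GLN = "polar", CYS = "polar",
    ALA = "aliphatic_hydrophobic", VAL = "aliphatic_hydrophobic",
    LEU = "aliphatic_hydrophobic", ILE = "aliphatic_hydrophobic",
    MET = "aliphatic_hydrophobic", PRO = "aliphatic_hydrophobic",
    PHE = "aromatic", TRP = "aromatic", TYR = "aromatic",
    GLY = "special")
  for (h in HIS_NAMES) category[h] <- "basic"

  # residues counting as "charged or polar" in the repulsion rule, with the
  # side-chain heteroatoms anchoring the distance measurement
  polar_anchor <- list(
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
    LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
    SER = "OG", THR = "OG1",
    ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"),
    TYR = "OH")
  for (h in HIS_NAMES) polar_anchor[[h]] <- c("ND1", "NE2")

  resnames <- unique(c(names(sidechain_carbons), HIS_NAMES))
  chem <- lapply(resnames, function(rn) {
    base <- if (rn %in% HIS_NAMES) "HIS" else rn
    list(
      basic_nitrogens = basic_nitrogens[[rn]] %||% character(0),
      acidic_oxygens = acidic_oxygens[[base]] %||% character(0),
      sidechain_carbons = sidechain_carbons[[base]] %||% character(0),
      hbond_donors = c(list(N = c("H", "HN")), donors[[rn]] %||% list()),
      hbond_acceptors = c("O", acceptors[[rn]] %||% character(0)),
      category = unname(category[rn]),
      polar_anchor = polar_anchor[[rn]] %||% character(0),
      include_termini = include_termini)
  })
  names(chem) <- resnames
  structure(chem, class = "cc_chemistry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Residue-level predicates used by the repulsion rule
is_aliphatic_hydrophobic <- function(resname, chem) {
  entry <- chem[[resname]]
  !is.null(entry) && identical(entry$category, "aliphatic_hydrophobic")
}
is_charged_or_polar <- function(resname, chem) {
  entry <- chem[[resname]]
  !is.null(entry) && length(entry$polar_anchor) > 0
}
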