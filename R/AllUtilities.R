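# Shared residue/atom chemistry tables.

.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
          MSE = "M")

.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

# Average residue masses (Da) for a residue *in chain* (monomer minus water);
# one water (18.02) is added per chain for the termini.
.RESIDUE_MASS <- c(
  A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14,
  E = 129.12, Q = 128.13, G = 57.05, H = 137.14, I = 113.16,
  L = 113.16, K = 128.17, M = 131.19, F = 147.18, P = 97.12,
  S = 87.08, T = 101.10, W = 186.21, Y = 163.18, V = 99.13)

.WATER_MASS <- 18.02

# sp2 / carbonyl-like carbons get the smaller NACCESS-style radius.
.SP2_CARBON <- list(
  ALL = "C",                      # backbone carbonyl carbon of any residue
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "CD2", "CE1"),
  ASP = "CG", ASN = "CG", GLU = "CD", GLN = "CD", ARG = "CZ")

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.oneLetter <- function(resnames) {
  out <- unname(.AA3[resnames])
  out[is.na(out)] <- "X"
  out
}

#' Van der Waals radii for SASA calculations
#'
#' NACCESS-like assignment: aliphatic carbon 1.87, carbonyl/aromatic (sp2)
#' carbon 1.76, nitrogen 1.65, oxygen 1.40, sulfur 1.85; anything else
#' falls back to 1.80 Angstrom. Hydrogens, if present, get 0 and are
#' normally excluded upstream.
#'
#' @param atoms atom data.frame with \code{element}, \code{name},
#'   \code{resname} columns.
#' @return numeric radius per atom (Angstrom).
#' @export
atomRadii <- function(atoms) {
  el <- toupper(atoms$element)
  r <- rep(1.80, nrow(atoms))
  r[el == "N"] <- 1.65
  r[el == "O"] <- 1.40
  r[el == "S"] <- 1.85
  r[el == "H"] <- 0.0
  isC <- el == "C"
  r[isC] <- 1.87
  sp2 <- atoms$name %in% .SP2_CARBON$ALL
  for (rn in setdiff(names(.SP2_CARBON), "ALL"))
    sp2 <- sp2 | (atoms$resname == rn & atoms$name %in% .SP2_CARBON[[rn]])
  r[isC & sp2] <- 1.76
  r
}

.residueKey <- function(atoms) {
  paste0(atoms$chain, ":", atoms$resseq,
         ifelse(atoms$icode == " " | atoms$icode == "", "", atoms$icode))
}

.stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
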