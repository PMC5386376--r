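# Parametric fixture generators: ideal helices, helix bundles, rigid
# and noisy copies, peptide-in-groove toy complexes with known contact
# geometry, and motif-bearing sequences. All generators are pure
# functions of their arguments (and seed); geometry is idealised, not
# energy-minimised - adequate for exercising superposition, surface and
# contact code, with no claim of physical realism.

# minimal side-chain geometries: atoms are laid out head-to-tail along
# the outward radial direction from the helix axis, with branch atoms
# offset sideways; (name, along, side) in Angstrom from CB
.SIDECHAINS <- list(
  ALA = list(),
  GLY = NULL,                      # no CB at all
  SER = list(c("OG", 1.4, 0)),
  THR = list(c("OG1", 1.4, 0.4), c("CG2", 1.4, -1.0)),
  CYS = list(c("SG", 1.8, 0)),
  VAL = list(c("CG1", 1.5, 0.8), c("CG2", 1.5, -0.8)),
  LEU = list(c("CG", 1.5, 0), c("CD1", 2.8, 0.8), c("CD2", 2.8, -0.8)),
  ILE = list(c("CG1", 1.5, 0.6), c("CG2", 1.5, -1.0), c("CD1", 2.9, 0.6)),
  MET = list(c("CG", 1.5, 0), c("SD", 3.0, 0), c("CE", 4.4, 0.6)),
  PHE = list(c("CG", 1.5, 0), c("CD1", 2.6, 1.2), c("CD2", 2.6, -1.2),
             c("CE1", 3.9, 1.2), c("CE2", 3.9, -1.2), c("CZ", 4.5, 0)),
  TYR = list(c("CG", 1.5, 0), c("CD1", 2.6, 1.2), c("CD2", 2.6, -1.2),
             c("CE1", 3.9, 1.2), c("CE2", 3.9, -1.2), c("CZ", 4.5, 0),
             c("OH", 5.9, 0)),
  TRP = list(c("CG", 1.5, 0), c("CD1", 2.6, 1.1), c("CD2", 2.6, -1.1),
             c("NE1", 3.9, 1.1), c("CE2", 3.9, -0.4), c("CE3", 3.2, -2.2),
             c("CZ2", 5.1, -0.8), c("CZ3", 4.4, -2.6), c("CH2", 5.4, -2.0)),
  ASP = list(c("CG", 1.5, 0), c("OD1", 2.6, 0.9), c("OD2", 2.6, -0.9)),
  GLU = list(c("CG", 1.5, 0), c("CD", 3.0, 0), c("OE1", 4.1, 0.9),
             c("OE2", 4.1, -0.9)),
  ASN = list(c("CG", 1.5, 0), c("OD1", 2.6, 0.9), c("ND2", 2.6, -0.9)),
  GLN = list(c("CG", 1.5, 0), c("CD", 3.0, 0), c("OE1", 4.1, 0.9),
             c("NE2", 4.1, -0.9)),
  LYS = list(c("CG", 1.5, 0), c("CD", 3.0, 0), c("CE", 4.5, 0),
             c("NZ", 5.9, 0)),
  ARG = list(c("CG", 1.5, 0), c("CD", 3.0, 0), c("NE", 4.4, 0),
             c("CZ", 5.7, 0), c("NH1", 6.8, 0.9), c("NH2", 6.8, -0.9)),
  HIS = list(c("CG", 1.5, 0), c("ND1", 2.6, 1.0), c("CD2", 2.6, -1.0),
             c("CE1", 3.9, 0.9), c("NE2", 3.9, -0.6)),
  PRO = list(c("CG", 1.4, 0.8), c("CD", 1.0, 1.9)))

.ONE2THREE <- setNames(names(.AA3)[1:20], unname(.AA3[1:20]))

#' Generate an ideal Calpha-trace helix
#'
#' Residue i's Calpha sits at (radius cos(i twist), radius sin(i twist),
#' i rise); defaults are ideal alpha-helix values (1.5 A rise, 100 deg
#' twist, 2.3 A radius), giving consecutive Calpha-Calpha distances of
#' about 3.8 A. With \code{sidechains = TRUE} each residue also gets a
#' CB and an idealised side-chain tip pointing radially outward, so
#' hydrogen-bond, salt-bridge and burial code has real atom names to
#' work with.
#'
#' @param nResidues number of residues (>= 3).
#' @param rise helical rise per residue (Angstrom).
#' @param twist rotation per residue (degrees).
#' @param radius helix radius (Angstrom).
#' @param sequence optional one-letter sequence (default poly-Ala).
#' @param chain chain identifier.
#' @param startRes first residue number.
#' @param sidechains build CB + side-chain pseudo-atoms (default FALSE:
#'   Calpha trace only).
#' @param id structure identifier.
#' @return a \linkS4class{PDBStructure}.
#' @export
makeHelix <- function(nResidues, rise = 1.5, twist = 100, radius = 2.3,
                      sequence = NULL, chain = "A", startRes = 1L,
                      sidechains = FALSE, id = "helix") {
  .stopIfNot(nResidues >= 3L, "a helix needs at least 3 residues")
  if (is.null(sequence)) sequence <- strrep("A", nResidues)
  .stopIfNot(nchar(sequence) == nResidues,
             "sequence length must equal nResidues")
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  res3 <- .ONE2THREE[letters1]
  .stopIfNot(!any(is.na(res3)), "sequence contains unknown residues")

  rows <- list()
  for (i in seq_len(nResidues)) {
    th <- (i - 1) * twist * pi / 180
    ca <- c(radius * cos(th), radius * sin(th), (i - 1) * rise)
    u <- c(cos(th), sin(th), 0)            # outward radial
    v <- c(-sin(th), cos(th), 0)           # tangential (branch direction)
    rn <- res3[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      name = "CA", resname = rn, chain = chain,
      resseq = startRes + i - 1L, x = ca[1], y = ca[2], z = ca[3])
    if (sidechains && rn != "GLY") {
      cb <- ca + 1.53 * u
      rows[[length(rows) + 1L]] <- data.frame(
        name = "CB", resname = rn, chain = chain,
        resseq = startRes + i - 1L, x = cb[1], y = cb[2], z = cb[3])
      for (sc in .SIDECHAINS[[rn]]) {
        p <- cb + as.numeric(sc[2]) * u + as.numeric(sc[3]) * v
        rows[[length(rows) + 1L]] <- data.frame(
          name = sc[1], resname = rn, chain = chain,
          resseq = startRes + i - 1L, x = p[1], y = p[2], z = p[3])
      }
    }
  }
  newStructure(do.call(rbind, rows), id = id)
}

#' Generate a helix bundle
#'
#' Places \code{nHelices} ideal helices on a circle of radius
#' \code{bundleRadius}, alternating their axial direction, as a compact
#' stand-in for the globular all-alpha bundle fold of Bcl-2-like
#' proteins. All helices share one chain with sequential numbering.
#'
#' @param nHelices number of helices (default 4).
#' @param resPerHelix residues per helix (default 15).
#' @param bundleRadius circle radius in Angstrom (default 6).
#' @param chain chain id.
#' @param sidechains passed to \code{\link{makeHelix}}.
#' @param id structure identifier.
#' @return a \linkS4class{PDBStructure}.
#' @export
makeBundle <- function(nHelices = 4L, resPerHelix = 15L,
                       bundleRadius = 6, chain = "A",
                       sidechains = FALSE, id = "bundle") {
  parts <- list()
  start <- 1L
  for (k in seq_len(nHelices)) {
    h <- makeHelix(resPerHelix, chain = chain, startRes = start,
                   sidechains = sidechains, id = id)
    a <- atomRecords(h)
    ang <- 2 * pi * (k - 1) / nHelices
    if (k %% 2L == 0L) a$z <- max(a$z) - a$z      # antiparallel
    a$x <- a$x + bundleRadius * cos(ang)
    a$y <- a$y + bundleRadius * sin(ang)
    parts[[k]] <- a
    start <- start + resPerHelix
  }
  atoms <- do.call(rbind, parts)
  atoms$serial <- seq_len(nrow(atoms))
  newStructure(atoms, id = id)
}

#' Add iid Gaussian coordinate noise
#'
#' Per-axis, per-atom N(0, sigma^2) displacement; seed-reproducible.
#'
#' @param structure a \linkS4class{PDBStructure}.
#' @param sigma noise SD per coordinate axis (Angstrom, >= 0).
#' @param seed integer RNG seed (optional).
#' @return a perturbed \linkS4class{PDBStructure}.
#' @export
perturbStructure <- function(structure, sigma, seed = NULL) {
  .stopIfNot(sigma >= 0, "sigma must be >= 0")
  if (sigma == 0) return(structure)
  if (!is.null(seed)) set.seed(seed)
  a <- atomRecords(structure)
  n <- nrow(a)
  a$x <- a$x + rnorm(n, 0, sigma)
  a$y <- a$y + rnorm(n, 0, sigma)
  a$z <- a$z + rnorm(n, 0, sigma)
  initialize(structure, atoms = a)
}

#' Apply a rigid motion to a structure
#'
#' @param structure a \linkS4class{PDBStructure}.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 vector (Angstrom).
#' @return the moved structure.
#' @export
rigidMove <- function(structure, rotation = diag(3),
                      translation = c(0, 0, 0)) {
  res <- new("SuperpositionResult", rotation = rotation,
             translation = translation, rmsd = 0,
             nPairs = 0L)
  applyTransform(structure, res)
}

#' Build a peptide-in-groove toy complex with known contacts
#'
#' The "peptide" (chain B) is an ideal side-chain-bearing helix; the
#' "receptor" (chain A) is built residue by residue from a contact plan,
#' so the ground truth is known by construction and returned alongside.
#' Plan entries are lists with a \code{type}:
#' \describe{
#'   \item{hbond}{\code{peptideRes} (a Ser/Thr/Tyr donor residue) gets a
#'     receptor Glu whose OE1 sits \code{dist} Angstrom beyond the
#'     donor tip along the outward direction.}
#'   \item{salt}{\code{peptideRes} (an Asp/Glu residue) gets a receptor
#'     Arg whose NH1 sits \code{dist} Angstrom from the acidic tip.}
#'   \item{pocket}{\code{peptideRes} gets its side chain enclosed by two
#'     concentric shells of receptor carbon pseudo-atoms (resname POC,
#'     flagged protein-like via ALA) centred on the side-chain centroid.}
#' }
#' Cross-chain atom pairs closer than 1.5 A abort with an infeasible-
#' placement error.
#'
#' @param peptideSequence one-letter sequence of the peptide helix.
#' @param plan list of contact-plan entries (see Details).
#' @param id structure identifier.
#' @return list with \code{structure} (a \linkS4class{PDBStructure})
#'   and \code{truth}: the planned hydrogen bonds, salt bridges and
#'   pocket residues with their target distances.
#' @export
makeGrooveComplex <- function(peptideSequence, plan = list(),
                              id = "groove") {
  pep <- makeHelix(nchar(peptideSequence), sequence = peptideSequence,
                   chain = "B", sidechains = TRUE, id = id)
  pa <- atomRecords(pep)
  recRows <- list()
  truth <- list(hbonds = data.frame(), saltBridges = data.frame(),
                pockets = integer(0))
  resCounter <- 0L

  tipOf <- function(resseq) {
    sub <- pa[pa$resseq == resseq, , drop = FALSE]
    .stopIfNot(nrow(sub) > 0L,
               paste("peptide residue", resseq, "not found"))
    tip <- sub[nrow(sub), ]                 # last atom = chain tip
    ca <- sub[sub$name == "CA", ]
    dir <- c(tip$x - ca$x, tip$y - ca$y, tip$z - ca$z)
    dir <- dir / sqrt(sum(dir^2))
    list(tip = tip, dir = dir, sub = sub)
  }
  addAtom <- function(name, resname, resseq, p) {
    recRows[[length(recRows) + 1L]] <<- data.frame(
      name = name, resname = resname, chain = "A", resseq = resseq,
      x = p[1], y = p[2], z = p[3])
  }

  for (entry in plan) {
    type <- entry$type
    t <- tipOf(entry$peptideRes)
    tp <- c(t$tip$x, t$tip$y, t$tip$z)
    if (type == "hbond") {
      d <- entry$dist %||% 2.9
      resCounter <- resCounter + 1L
      oe1 <- tp + d * t$dir
      addAtom("OE1", "GLU", resCounter, oe1)
      addAtom("CD", "GLU", resCounter, oe1 + 1.25 * t$dir)
      addAtom("OE2", "GLU", resCounter, oe1 + 1.25 * t$dir + c(0, 0, 1.1))
      addAtom("CA", "GLU", resCounter, oe1 + 4.0 * t$dir)
      truth$hbonds <- rbind(truth$hbonds, data.frame(
        peptideRes = entry$peptideRes, donorAtom = t$tip$name,
        acceptorAtom = "OE1", dist = d))
    } else if (type == "salt") {
      d <- entry$dist %||% 3.2
      resCounter <- resCounter + 1L
      nh1 <- tp + d * t$dir
      addAtom("NH1", "ARG", resCounter, nh1)
      addAtom("CZ", "ARG", resCounter, nh1 + 1.33 * t$dir)
      addAtom("NH2", "ARG", resCounter, nh1 + 1.33 * t$dir + c(0, 0, 1.2))
      addAtom("CA", "ARG", resCounter, nh1 + 5.0 * t$dir)
      truth$saltBridges <- rbind(truth$saltBridges, data.frame(
        peptideRes = entry$peptideRes, basicAtom = "NH1",
        acidicAtom = t$tip$name, dist = d))
    } else if (type == "pocket") {
      rad <- entry$shellRadius %||% 4.5
      sc <- t$sub[!(t$sub$name %in% .BACKBONE_ATOMS), , drop = FALSE]
      ctr <- colMeans(sc[, c("x", "y", "z")])
      for (r in c(rad, rad + 1.3)) {
        pts <- sweep(.goldenSpiral(entry$nShell %||% 120L) * r, 2, ctr, "+")
        # drop shell atoms clashing with the peptide itself
        keepPt <- apply(pts, 1, function(p)
          min(sqrt((pa$x - p[1])^2 + (pa$y - p[2])^2 +
                   (pa$z - p[3])^2)) >= 2.5)
        for (ii in which(keepPt)) {
          resCounter <- resCounter + 1L
          addAtom("CB", "ALA", resCounter, pts[ii, ])
        }
      }
      truth$pockets <- c(truth$pockets, entry$peptideRes)
    } else stop("unknown plan entry type: ", type, call. = FALSE)
  }

  atoms <- if (length(recRows))
    rbind(do.call(rbind, recRows), pa[, c("name", "resname", "chain",
                                          "resseq", "x", "y", "z")])
  else pa[, c("name", "resname", "chain", "resseq", "x", "y", "z")]
  atoms$serial <- seq_len(nrow(atoms))
  cplx <- newStructure(atoms, id = id)

  # clash check across chains
  a <- atomRecords(cplx)
  A <- a[a$chain == "A", c("x", "y", "z")]
  B <- a[a$chain == "B", c("x", "y", "z")]
  if (nrow(A) && nrow(B)) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") -
      2 * as.matrix(A) %*% t(as.matrix(B))
    if (min(d2) < 1.5^2)
      stop("infeasible placement: cross-chain clash below 1.5 Angstrom",
           call. = FALSE)
  }
  list(structure = cplx, truth = truth)
}

#' Generate a sequence with embedded BH3 consensus motifs
#'
#' Embeds the V-x3-L-x2-F-x-D-x-V spacing template at the given
#' position(s); flanking residues are drawn from a composition that
#' scores zero at every template position, so the embedded motifs are
#' the only hits by construction.
#'
#' @param positions 1-based h1 position(s) of the motif(s).
#' @param length total sequence length (default: last motif end + 10).
#' @param flankAlphabet residues used for flanks (default small/polar
#'   set with no hydrophobic or acidic members).
#' @param template residues at (h1, h2, h3, acid, h4).
#' @param seed RNG seed for the flanks.
#' @return character sequence.
#' @export
makeBH3Sequence <- function(positions, length = NULL,
                            flankAlphabet = c("G", "S", "T", "N", "Q",
                                              "P", "K", "R"),
                            template = c("V", "L", "F", "D", "V"),
                            seed = 1L) {
  .stopIfNot(all(positions >= 1), "positions must be >= 1")
  if (is.null(length)) length <- max(positions) + .BH3_SPAN - 1L + 10L
  .stopIfNot(max(positions) + .BH3_SPAN - 1L <= length,
             "motif does not fit in the requested length")
  set.seed(seed)
  chars <- sample(flankAlphabet, length, replace = TRUE)
  offs <- .BH3_OFFSETS[c("h1", "h2", "h3", "acid", "h4")]
  for (p in positions) chars[p + offs] <- template
  paste(chars, collapse = "")
}
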