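# Polar-contact and hot-spot analysis of receptor:peptide interfaces.
# All geometry is heavy-atom based: crystal structures of this kind carry
# no hydrogens, so hydrogen bonds are identified by donor-acceptor
# distance plus the angle at the donor measured via its covalent
# antecedent.

# donor atoms and their antecedent (same residue); "*" = any amino acid
.HB_DONORS <- data.frame(
  resname = c("*", "ARG", "ARG", "ARG", "LYS", "HIS", "HIS", "TRP",
              "ASN", "GLN", "SER", "THR", "TYR", "CYS"),
  atom = c("N", "NE", "NH1", "NH2", "NZ", "ND1", "NE2", "NE1",
           "ND2", "NE2", "OG", "OG1", "OH", "SG"),
  antecedent = c("CA", "CD", "CZ", "CZ", "CE", "CG", "CE1", "CD1",
                 "CG", "CD", "CB", "CB", "CZ", "CB"),
  stringsAsFactors = FALSE)

.HB_ACCEPTORS <- data.frame(
  resname = c("*", "*", "ASP", "ASP", "GLU", "GLU", "ASN", "GLN",
              "SER", "THR", "TYR", "HIS", "HIS", "MET"),
  atom = c("O", "OXT", "OD1", "OD2", "OE1", "OE2", "OD1", "OE1",
           "OG", "OG1", "OH", "ND1", "NE2", "SD"),
  stringsAsFactors = FALSE)

.SB_BASIC <- data.frame(
  resname = c("ARG", "ARG", "ARG", "LYS", "HIS", "HIS"),
  atom = c("NH1", "NH2", "NE", "NZ", "ND1", "NE2"),
  stringsAsFactors = FALSE)

.SB_ACIDIC <- data.frame(
  resname = c("ASP", "ASP", "GLU", "GLU"),
  atom = c("OD1", "OD2", "OE1", "OE2"),
  stringsAsFactors = FALSE)

.matchRole <- function(atoms, table) {
  hit <- rep(FALSE, nrow(atoms))
  for (k in seq_len(nrow(table))) {
    rn <- table$resname[k]
    sel <- atoms$name == table$atom[k] &
      (rn == "*" | atoms$resname == rn) & atoms$kind == "protein"
    if (rn == "*" && table$atom[k] == "N")
      sel <- sel & atoms$resname != "PRO"   # proline N has no H
    hit <- hit | sel
  }
  which(hit)
}

.atomID <- function(atoms, idx) {
  paste0(atoms$chain[idx], ":", atoms$resname[idx], atoms$resseq[idx],
         ":", atoms$name[idx])
}

#' Hydrogen bonds across a two-body interface
#'
#' Cross-interface donor-acceptor pairs among N/O/S polar atoms with
#' donor-acceptor distance <= \code{dMax} and
#' antecedent-donor-acceptor angle >= \code{angleMin} (heavy-atom
#' criterion; explicit hydrogens are not required). When a donor's
#' antecedent atom is missing from the model the angle test is waived
#' for that donor and the angle reported as NA.
#'
#' @param complex a \linkS4class{PDBStructure}.
#' @param partA,partB disjoint chain sets.
#' @param dMax distance cutoff in Angstrom (default 3.5).
#' @param angleMin minimum angle at the donor in degrees (default 90).
#' @return data.frame with donor, acceptor, distance, angle columns
#'   (zero rows when no bonds are found).
#' @export
findHBonds <- function(complex, partA, partB, dMax = 3.5, angleMin = 90) {
  a <- atomRecords(complex)
  don <- .matchRole(a, .HB_DONORS)
  acc <- .matchRole(a, .HB_ACCEPTORS)
  out <- rbind(
    .hbondsOneWay(a, don[a$chain[don] %in% partA],
                  acc[a$chain[acc] %in% partB], dMax, angleMin),
    .hbondsOneWay(a, don[a$chain[don] %in% partB],
                  acc[a$chain[acc] %in% partA], dMax, angleMin))
  out[!duplicated(paste(out$donor, out$acceptor)), , drop = FALSE]
}

.hbondsOneWay <- function(a, don, acc, dMax, angleMin) {
  empty <- data.frame(donor = character(0), acceptor = character(0),
                      donorResidue = character(0),
                      acceptorResidue = character(0),
                      distance = numeric(0), angle = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(don) || !length(acc)) return(empty)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rows <- list()
  for (d in don) {
    dv <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[d, ])^2))
    close <- acc[dv <= dMax]
    if (!length(close)) next
    antName <- .HB_DONORS$antecedent[
      match(TRUE, (.HB_DONORS$resname == "*" |
                   .HB_DONORS$resname == a$resname[d]) &
                  .HB_DONORS$atom == a$name[d])]
    ant <- which(a$chain == a$chain[d] & a$resseq == a$resseq[d] &
                 a$icode == a$icode[d] & a$name == antName)
    for (ac in close) {
      dist <- sqrt(sum((xyz[ac, ] - xyz[d, ])^2))
      ang <- NA_real_
      if (length(ant) == 1L) {
        v1 <- xyz[ant, ] - xyz[d, ]
        v2 <- xyz[ac, ] - xyz[d, ]
        ang <- acos(pmin(1, pmax(-1,
          sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang < angleMin) next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        donor = .atomID(a, d), acceptor = .atomID(a, ac),
        donorResidue = paste0(a$chain[d], ":", a$resname[d], a$resseq[d]),
        acceptorResidue = paste0(a$chain[ac], ":", a$resname[ac],
                                 a$resseq[ac]),
        distance = dist, angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Salt bridges across a two-body interface
#'
#' Basic-group nitrogens (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2) paired
#' with acidic-group oxygens (Asp OD1/OD2, Glu OE1/OE2) across the
#' interface within \code{dMax}.
#'
#' @param complex a \linkS4class{PDBStructure}.
#' @param partA,partB disjoint chain sets.
#' @param dMax distance cutoff in Angstrom (default 4.0).
#' @return data.frame with basic, acidic, distance columns.
#' @export
findSaltBridges <- function(complex, partA, partB, dMax = 4.0) {
  a <- atomRecords(complex)
  bas <- .matchRole(a, .SB_BASIC)
  aci <- .matchRole(a, .SB_ACIDIC)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pairUp <- function(b, c) {
    if (!length(b) || !length(c)) return(NULL)
    g <- expand.grid(b = b, c = c)
    d <- sqrt(rowSums((xyz[g$b, , drop = FALSE] -
                       xyz[g$c, , drop = FALSE])^2))
    keep <- d <= dMax
    if (!any(keep)) return(NULL)
    data.frame(basic = .atomID(a, g$b[keep]),
               acidic = .atomID(a, g$c[keep]),
               basicResidue = paste0(a$chain[g$b[keep]], ":",
                                     a$resname[g$b[keep]],
                                     a$resseq[g$b[keep]]),
               acidicResidue = paste0(a$chain[g$c[keep]], ":",
                                      a$resname[g$c[keep]],
                                      a$resseq[g$c[keep]]),
               distance = d[keep], stringsAsFactors = FALSE)
  }
  out <- rbind(
    pairUp(bas[a$chain[bas] %in% partA], aci[a$chain[aci] %in% partB]),
    pairUp(bas[a$chain[bas] %in% partB], aci[a$chain[aci] %in% partA]))
  if (is.null(out))
    out <- data.frame(basic = character(0), acidic = character(0),
                      basicResidue = character(0),
                      acidicResidue = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  out[!duplicated(paste(out$basic, out$acidic)), , drop = FALSE]
}

#' Side-chain burial of BH3 hot-spot residues
#'
#' For each hot-spot residue of the peptide, compares its side-chain SASA
#' in the isolated peptide (at complex coordinates) with that in the
#' complex; burial fraction = 1 - complexed/free. A residue is classified
#' "engaged" when its burial fraction reaches \code{threshold} - the
#' classification is reported as data, not as a hard claim about pocket
#' chemistry.
#'
#' @param complex a \linkS4class{PDBStructure}.
#' @param receptorChains,peptideChain chain partition.
#' @param hotspots integer vector of peptide residue numbers (resseq).
#' @param params a \linkS4class{SASAParams}.
#' @param threshold engaged classification threshold (default 0.7).
#' @return data.frame with residue number, name, free and complexed
#'   side-chain areas, burial fraction and engaged flag.
#' @export
hotspotBurial <- function(complex, receptorChains, peptideChain, hotspots,
                          params = sasaParams(), threshold = 0.7) {
  a <- atomRecords(complex)
  a <- a[a$kind == "protein", , drop = FALSE]
  pep <- a$chain == peptideChain
  keep <- pep | a$chain %in% receptorChains
  .stopIfNot(any(pep), paste0("peptide chain '", peptideChain, "' absent"))
  miss <- setdiff(hotspots, unique(a$resseq[pep]))
  .stopIfNot(length(miss) == 0L,
             paste("hot-spot residue(s) absent from peptide chain:",
                   paste(miss, collapse = ", ")))
  # shared quadrature frame so free/complexed areas differ only by real
  # occlusion, not quadrature orientation
  fr <- .molecularFrame(as.matrix(a[keep, c("x", "y", "z")]))
  sFree <- sasa(a[pep, , drop = FALSE], params, frame = fr)
  sCplx <- sasa(a[keep, , drop = FALSE], params, frame = fr)
  freeAtoms <- a[pep, , drop = FALSE]
  cplxAtoms <- a[keep, , drop = FALSE]
  rows <- lapply(hotspots, function(rs) {
    scFree <- freeAtoms$resseq == rs &
      !(freeAtoms$name %in% .BACKBONE_ATOMS)
    scCplx <- cplxAtoms$chain == peptideChain & cplxAtoms$resseq == rs &
      !(cplxAtoms$name %in% .BACKBONE_ATOMS)
    rn <- freeAtoms$resname[freeAtoms$resseq == rs][1]
    if (!any(scFree)) {
      warning("hot-spot residue ", rn, rs,
              " has no side-chain atoms (glycine?); zero areas reported",
              call. = FALSE)
      return(data.frame(residue = rs, resname = rn, freeArea = 0,
                        complexArea = 0, burial = 0, engaged = FALSE))
    }
    fr <- sum(perAtomArea(sFree)[scFree])
    cx <- sum(perAtomArea(sCplx)[scCplx])
    burial <- if (fr > 0) max(0, min(1, 1 - cx / fr)) else 0
    data.frame(residue = rs, resname = rn, freeArea = fr,
               complexArea = cx, burial = burial,
               engaged = burial >= threshold)
  })
  do.call(rbind, rows)
}

#' Full interface report of a receptor:peptide complex
#'
#' Combines \code{\link{buriedSurface}}, \code{\link{findHBonds}},
#' \code{\link{findSaltBridges}} and (when hot-spot residues are given)
#' \code{\link{hotspotBurial}} into a single
#' \linkS4class{InterfaceReport}.
#'
#' @param complex a \linkS4class{PDBStructure}.
#' @param receptorChains,peptideChain chain partition.
#' @param hotspots optional integer vector of peptide residue numbers.
#' @param params a \linkS4class{SASAParams}.
#' @param hbondDMax,hbondAngleMin,saltDMax geometric criteria.
#' @param burialThreshold hot-spot engaged threshold.
#' @return an \linkS4class{InterfaceReport}.
#' @export
interfaceReport <- function(complex, receptorChains, peptideChain,
                            hotspots = NULL, params = sasaParams(),
                            hbondDMax = 3.5, hbondAngleMin = 90,
                            saltDMax = 4.0, burialThreshold = 0.7) {
  rep0 <- buriedSurface(complex, receptorChains, peptideChain, params)
  hb <- findHBonds(complex, receptorChains, peptideChain,
                   dMax = hbondDMax, angleMin = hbondAngleMin)
  sb <- findSaltBridges(complex, receptorChains, peptideChain,
                        dMax = saltDMax)
  hs <- if (is.null(hotspots)) data.frame() else
    hotspotBurial(complex, receptorChains, peptideChain, hotspots,
                  params, burialThreshold)
  initialize(rep0, hbonds = hb, saltBridges = sb, hotspots = hs)
}
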