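#' Read a PDB-format coordinate file
#'
#' Parses fixed-width ATOM/HETATM records of one model into a
#' \linkS4class{PDBStructure}. Alternate locations are collapsed
#' deterministically (highest occupancy wins; ties go to the
#' alphabetically first altloc). Waters and non-protein heteroatoms are
#' retained but flagged via the \code{kind} column so surface and
#' interface code can exclude them. Missing element columns (77-78) are
#' inferred from the atom-name convention used by older PDB dialects.
#'
#' @param path file path of a PDB-format file.
#' @param model integer model to extract (default 1; crystal structures
#'   have a single model).
#' @param collapseAltloc collapse alternate locations (default TRUE).
#' @return a \linkS4class{PDBStructure}.
#' @examples
#' h <- makeHelix(8)
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(h, f)
#' readStructure(f)
#' @export
readStructure <- function(path, model = 1L, collapseAltloc = TRUE) {
  .stopIfNot(file.exists(path), paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  .stopIfNot(any(isAtom),
             paste0("no ATOM/HETATM records in '", path, "'"))

  # model bookkeeping: atoms between MODEL k and ENDMDL belong to model k
  curModel <- 1L
  modelOf <- integer(length(lines))
  sawModel <- FALSE
  for (i in which(rec %in% c("MODEL ", "ENDMDL") | isAtom)) {
    r <- rec[i]
    if (r == "MODEL ") {
      curModel <- suppressWarnings(as.integer(substr(lines[i], 11, 14)))
      if (is.na(curModel)) curModel <- 1L
      sawModel <- TRUE
    } else if (r == "ENDMDL") {
      curModel <- curModel + 1L
    } else {
      modelOf[i] <- curModel
    }
  }
  idx <- which(isAtom & (if (sawModel) modelOf == model else TRUE))
  if (!length(idx))
    stop("empty structure: no atoms in model ", model, " of '", path, "'",
         call. = FALSE)

  ln <- lines[idx]
  short <- nchar(ln) < 54
  if (any(short))
    stop("malformed fixed-width record at line ", idx[which(short)[1]],
         ": fewer than 54 columns", call. = FALSE)
  fld <- function(from, to) substr(ln, from, to)
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)))
    if (length(bad))
      stop("malformed ", what, " at line ", idx[bad[1]], call. = FALSE)
    v
  }
  x <- num(fld(31, 38), "x coordinate")
  y <- num(fld(39, 46), "y coordinate")
  z <- num(fld(47, 54), "z coordinate")
  if (any(!is.finite(c(x, y, z))))
    stop("malformed coordinates at line ",
         idx[which(!is.finite(x) | !is.finite(y) | !is.finite(z))[1]],
         call. = FALSE)
  occ <- num(fld(55, 60), "occupancy"); occ[is.na(occ)] <- 1
  bf <- num(fld(61, 66), "B-factor"); bf[is.na(bf)] <- 0

  name <- trimws(fld(13, 16))
  element <- trimws(fld(77, 78))
  infer <- !nzchar(element)
  if (any(infer)) {
    stripped <- sub("^[0-9']+", "", name[infer])
    element[infer] <- toupper(substr(stripped, 1, 1))
  }
  resname <- trimws(fld(18, 20))
  recType <- trimws(fld(1, 6))
  kind <- ifelse(resname %in% .WATER_NAMES, "water",
          ifelse(resname %in% names(.AA3), "protein", "hetero"))

  atoms <- data.frame(
    serial = suppressWarnings(as.integer(fld(7, 11))),
    name = name,
    altloc = fld(17, 17),
    resname = resname,
    chain = fld(22, 22),
    resseq = suppressWarnings(as.integer(fld(23, 26))),
    icode = fld(27, 27),
    x = x, y = y, z = z,
    occupancy = pmin(pmax(occ, 0), 1),
    bfactor = bf,
    element = element,
    kind = kind,
    stringsAsFactors = FALSE)

  if (collapseAltloc) atoms <- .collapseAltloc(atoms)
  new("PDBStructure",
      id = sub("\\.[^.]*$", "", basename(path)),
      atoms = atoms, model = as.integer(model))
}

# keep, per (chain, resseq, icode, name), the altloc with the highest
# occupancy; ties broken by the alphabetically first altloc code.
.collapseAltloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name)
  o <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[o, , drop = FALSE]
  atoms <- atoms[!duplicated(key[o]), , drop = FALSE]
  atoms <- atoms[order(atoms$chain, atoms$resseq, atoms$icode, atoms$serial), ,
                 drop = FALSE]
  atoms$altloc <- " "
  rownames(atoms) <- NULL
  atoms
}

#' Write a structure as fixed-width PDB records
#'
#' Emits ATOM/HETATM records (HETATM for waters and heteroatoms), TER at
#' chain boundaries and END. Coordinates outside the 8.3 fixed-width
#' field (|x| > 9999.999 or x < -999.999) raise a formatted-overflow
#' error instead of corrupting columns.
#'
#' @param structure a \linkS4class{PDBStructure}.
#' @param path destination file path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(structure, path) {
  a <- atomRecords(structure)
  .stopIfNot(nrow(a) > 0L, "cannot write an empty structure")
  if (any(a$x > 9999.999 | a$x < -999.999 |
          a$y > 9999.999 | a$y < -999.999 |
          a$z > 9999.999 | a$z < -999.999))
    stop("formatted overflow: coordinates do not fit the 8.3 PDB field",
         call. = FALSE)
  padName <- ifelse(nchar(a$name) <= 3L, paste0(" ", a$name), a$name)
  recType <- ifelse(a$kind == "protein", "ATOM  ", "HETATM")
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    recType, a$serial %% 100000L, padName, a$altloc, a$resname, a$chain,
    a$resseq, a$icode, a$x, a$y, a$z, a$occupancy, a$bfactor,
    toupper(a$element))
  # TER after the last atom of each chain
  out <- character(0)
  for (ch in unique(a$chain)) {
    out <- c(out, lines[a$chain == ch], "TER")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Extract ordered Calpha coordinates of one chain
#'
#' Returns one Calpha per protein residue of the chain, in residue order
#' (resseq, then insertion code). Residues lacking a Calpha are omitted
#' with a warning.
#'
#' @param structure a \linkS4class{PDBStructure}.
#' @param chain single chain identifier.
#' @return a \linkS4class{CoordSet}.
#' @export
selectCA <- function(structure, chain) {
  a <- atomRecords(structure)
  avail <- unique(a$chain)
  if (!chain %in% avail)
    stop("chain '", chain, "' not found; available: ",
         paste(avail, collapse = ", "), call. = FALSE)
  p <- a[a$chain == chain & a$kind == "protein", , drop = FALSE]
  .stopIfNot(nrow(p) > 0L, paste0("chain '", chain, "' has no protein atoms"))
  p <- p[order(p$resseq, p$icode), , drop = FALSE]
  resKey <- paste(p$resseq, p$icode)
  ca <- p[p$name == "CA", , drop = FALSE]
  missing <- setdiff(unique(resKey), paste(ca$resseq, ca$icode))
  if (length(missing))
    warning(length(missing), " residue(s) in chain '", chain,
            "' lack a Calpha and were omitted", call. = FALSE)
  .stopIfNot(nrow(ca) > 0L, paste0("chain '", chain, "' has no Calpha atoms"))
  new("CoordSet",
      labels = .residueKey(ca),
      resnames = ca$resname,
      coords = as.matrix(ca[, c("x", "y", "z")]))
}

#' Subset a structure by chain
#'
#' @param structure a \linkS4class{PDBStructure}.
#' @param chains character vector of chain ids to keep.
#' @return a \linkS4class{PDBStructure} with only those chains.
#' @export
selectChains <- function(structure, chains) {
  a <- atomRecords(structure)
  miss <- setdiff(chains, unique(a$chain))
  .stopIfNot(length(miss) == 0L,
             paste("chain(s) not present:", paste(miss, collapse = ", ")))
  keep <- a[a$chain %in% chains, , drop = FALSE]
  rownames(keep) <- NULL
  initialize(structure, atoms = keep)
}

#' Build a structure from an atom table
#'
#' Low-level constructor used by the synthetic generators; fills in
#' defaults for optional columns.
#'
#' @param atoms data.frame with at least \code{name}, \code{resname},
#'   \code{chain}, \code{resseq}, \code{x}, \code{y}, \code{z}.
#' @param id identifier string.
#' @return a \linkS4class{PDBStructure}.
#' @export
newStructure <- function(atoms, id = "model") {
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$altloc)) atoms$altloc <- " "
  if (is.null(atoms$icode)) atoms$icode <- " "
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$bfactor)) atoms$bfactor <- 0
  if (is.null(atoms$element)) {
    stripped <- sub("^[0-9']+", "", atoms$name)
    atoms$element <- toupper(substr(stripped, 1, 1))
  }
  if (is.null(atoms$kind))
    atoms$kind <- ifelse(atoms$resname %in% .WATER_NAMES, "water",
                  ifelse(atoms$resname %in% names(.AA3), "protein", "hetero"))
  atoms <- atoms[, c("serial", "name", "altloc", "resname", "chain",
                     "resseq", "icode", "x", "y", "z", "occupancy",
                     "bfactor", "element", "kind")]
  rownames(atoms) <- NULL
  new("PDBStructure", id = id, atoms = atoms, model = 1L)
}
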