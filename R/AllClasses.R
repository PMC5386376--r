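#' @import methods
NULL

#' PDBStructure: a single-model protein coordinate set
#'
#' Container for the atoms of one model of a PDB-format coordinate file.
#' Atoms are stored as a data.frame with one row per atom and the classic
#' fixed-width PDB fields; every atom is classified as \code{"protein"},
#' \code{"water"} or \code{"hetero"} so that downstream surface and
#' interface calculations can exclude solvent and ligands by default.
#'
#' @slot id character identifier (typically the file stem or PDB code).
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{altloc}, \code{resname}, \code{chain}, \code{resseq},
#'   \code{icode}, \code{x}, \code{y}, \code{z}, \code{occupancy},
#'   \code{bfactor}, \code{element}, \code{kind}.
#' @slot model integer model index the atoms came from.
#'
#' @exportClass PDBStructure
setClass("PDBStructure",
  representation(id = "character", atoms = "data.frame", model = "integer"),
  prototype(id = NA_character_, model = 1L))

setValidity("PDBStructure", function(object) {
  a <- object@atoms
  req <- c("serial", "name", "altloc", "resname", "chain", "resseq",
           "icode", "x", "y", "z", "occupancy", "bfactor", "element", "kind")
  if (!all(req %in% names(a)))
    return(paste("atoms table lacks columns:",
                 paste(setdiff(req, names(a)), collapse = ", ")))
  if (nrow(a) == 0L) return(TRUE)
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (any(a$occupancy < 0 | a$occupancy > 1))
    return("occupancy outside [0, 1]")
  if (any(!nzchar(a$element)))
    return("empty element symbol after inference")
  key <- paste(a$chain, a$resseq, a$icode, a$name, a$altloc)
  if (anyDuplicated(key))
    return("duplicate (chain, resseq, icode, name, altloc) atom identity")
  if (!all(a$kind %in% c("protein", "water", "hetero")))
    return("atom kind must be protein/water/hetero")
  TRUE
})

#' CoordSet: labelled Calpha (or other) coordinates
#'
#' @slot labels character residue keys, "chain:resseq[icode]".
#' @slot resnames character 3-letter residue names, parallel to labels.
#' @slot coords numeric N x 3 matrix of coordinates in Angstrom.
#'
#' @exportClass CoordSet
setClass("CoordSet",
  representation(labels = "character", resnames = "character",
                 coords = "matrix"))

setValidity("CoordSet", function(object) {
  if (ncol(object@coords) != 3L) return("coords must have 3 columns")
  if (nrow(object@coords) < 1L) return("coords must have at least one row")
  if (length(object@labels) != nrow(object@coords))
    return("label count must equal coordinate row count")
  if (length(object@resnames) != length(object@labels))
    return("resnames must parallel labels")
  if (!all(is.finite(object@coords))) return("non-finite coordinates")
  TRUE
})

#' SuperpositionResult: optimal rigid-body transform and its RMSD
#'
#' Rotation and translation mapping a moving coordinate set onto a fixed
#' one, with the root-mean-square deviation over the paired atoms after
#' applying the transform. For the iterative aligner, \code{pairs} holds the
#' final residue correspondence.
#'
#' @slot rotation 3 x 3 proper rotation matrix.
#' @slot translation numeric length-3 translation (Angstrom).
#' @slot rmsd numeric RMSD in Angstrom.
#' @slot nPairs integer number of paired atoms.
#' @slot pairs data.frame correspondence (may be empty).
#' @slot iterations integer iterations used (0 for direct Kabsch).
#' @slot converged logical whether iterative pairing stabilised.
#'
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nPairs = "integer",
                 pairs = "data.frame", iterations = "integer",
                 converged = "logical"),
  prototype(pairs = data.frame(), iterations = 0L, converged = TRUE))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation is not orthonormal within 1e-8")
  if (abs(det(R) - 1) > 1e-8)
    return("rotation determinant is not +1 within 1e-8")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

#' StructureAlignment: a gapped MSA with structures mapped onto rows
#'
#' Rows are gapped one-letter sequences of the *modelled* residues of each
#' chain (in the order the Calpha atoms occur); each row is mapped to a
#' structure and chain so that alignment columns can be translated into
#' equivalent Calpha pairs.
#'
#' @slot ids character row identifiers.
#' @slot seqs named character gapped sequences (equal width).
#' @slot structures named list of \code{PDBStructure}.
#' @slot chains named character chain id per row.
#'
#' @exportClass StructureAlignment
setClass("StructureAlignment",
  representation(ids = "character", seqs = "character",
                 structures = "list", chains = "character"))

setValidity("StructureAlignment", function(object) {
  if (length(object@seqs) != length(object@ids))
    return("one gapped sequence per id required")
  if (length(unique(nchar(object@seqs))) > 1L)
    return("gapped sequences must share a common width")
  mapped <- names(object@structures)
  if (!all(mapped %in% object@ids))
    return("structure map refers to unknown ids")
  if (!all(mapped %in% names(object@chains)))
    return("every mapped structure needs a chain id")
  TRUE
})

#' SASAParams: Shrake-Rupley quadrature parameters
#'
#' @slot probeRadius numeric solvent probe radius in Angstrom (default 1.4).
#' @slot spherePoints integer quadrature points per atom (default 960).
#'
#' @exportClass SASAParams
setClass("SASAParams",
  representation(probeRadius = "numeric", spherePoints = "integer"),
  prototype(probeRadius = 1.4, spherePoints = 960L))

setValidity("SASAParams", function(object) {
  if (object@probeRadius < 0) return("probe radius must be >= 0")
  if (object@spherePoints < 60L) return("need at least 60 sphere points")
  TRUE
})

#' SASAResult: per-atom, per-residue and total accessible area
#'
#' @slot perAtom numeric area per atom (Angstrom^2), parallel to the atom
#'   subset the calculation ran on.
#' @slot perResidue named numeric area per residue key.
#' @slot total numeric total area.
#' @slot atomKeys character residue key per atom (for aggregation checks).
#'
#' @exportClass SASAResult
setClass("SASAResult",
  representation(perAtom = "numeric", perResidue = "numeric",
                 total = "numeric", atomKeys = "character"))

setValidity("SASAResult", function(object) {
  if (any(object@perAtom < -1e-9)) return("negative per-atom area")
  if (abs(sum(object@perAtom) - object@total) > 1e-6)
    return("total does not equal sum of per-atom areas")
  if (abs(sum(object@perResidue) - object@total) > 1e-6)
    return("total does not equal sum of per-residue areas")
  TRUE
})

#' InterfaceReport: buried surface and polar contacts of a two-body complex
#'
#' Buried area is reported under both common conventions: the total
#' solvent-accessible surface lost on complex formation
#' (SASA(A) + SASA(B) - SASA(AB)) and its half, the PISA-style
#' "interface area".
#'
#' @slot buriedTotal numeric total buried SASA (Angstrom^2).
#' @slot buriedPerPartner numeric length-2 split (receptor, ligand).
#' @slot interfaceArea numeric buriedTotal / 2.
#' @slot hbonds data.frame hydrogen bonds across the interface.
#' @slot saltBridges data.frame salt bridges across the interface.
#' @slot hotspots data.frame per-hot-spot side-chain burial.
#'
#' @exportClass InterfaceReport
setClass("InterfaceReport",
  representation(buriedTotal = "numeric", buriedPerPartner = "numeric",
                 interfaceArea = "numeric", hbonds = "data.frame",
                 saltBridges = "data.frame", hotspots = "data.frame"),
  prototype(hbonds = data.frame(), saltBridges = data.frame(),
            hotspots = data.frame()))

setValidity("InterfaceReport", function(object) {
  if (object@buriedTotal < -1e-6) return("buried area must be >= 0")
  if (length(object@buriedPerPartner) != 2L)
    return("buriedPerPartner must have two entries")
  if (abs(sum(object@buriedPerPartner) - object@buriedTotal) > 1e-6)
    return("partner split must sum to the buried total")
  TRUE
})

#' ITCExperiment: titration protocol and (optionally) per-injection heats
#'
#' Defaults mirror a MicroCal iTC200-style experiment: a 204.4 ul cell and
#' a syringe titrating small injections of ligand into the macromolecule.
#'
#' @slot cellVolume numeric working cell volume in microlitres.
#' @slot cellConc numeric macromolecule concentration in the cell (M).
#' @slot syringeConc numeric ligand concentration in the syringe (M).
#' @slot injectionVolumes numeric per-injection volumes (ul).
#' @slot temperature numeric temperature in Celsius.
#' @slot heats numeric measured/simulated per-injection heats (ucal);
#'   length 0 for a protocol-only object.
#'
#' @exportClass ITCExperiment
setClass("ITCExperiment",
  representation(cellVolume = "numeric", cellConc = "numeric",
                 syringeConc = "numeric", injectionVolumes = "numeric",
                 temperature = "numeric", heats = "numeric"),
  prototype(cellVolume = 204.4, temperature = 25, heats = numeric(0)))

setValidity("ITCExperiment", function(object) {
  if (object@cellVolume <= 0) return("cell volume must be positive")
  if (object@cellConc <= 0 || object@syringeConc <= 0)
    return("concentrations must be positive")
  if (length(object@injectionVolumes) < 1L ||
      any(object@injectionVolumes <= 0))
    return("injection volumes must be positive")
  if (length(object@heats) > 0L &&
      length(object@heats) != length(object@injectionVolumes))
    return("heats length must match injection count")
  TRUE
})

#' ITCModelParams: single-site binding model parameters
#'
#' @slot N numeric stoichiometry (sites per macromolecule).
#' @slot Ka numeric association constant (1/M); Kd = 1/Ka.
#' @slot dH numeric binding enthalpy (cal/mol).
#' @slot baseline numeric per-injection heat offset (ucal).
#'
#' @exportClass ITCModelParams
setClass("ITCModelParams",
  representation(N = "numeric", Ka = "numeric", dH = "numeric",
                 baseline = "numeric"),
  prototype(baseline = 0))

setValidity("ITCModelParams", function(object) {
  if (object@N <= 0) return("N must be > 0")
  if (object@Ka <= 0) return("Ka must be > 0")
  TRUE
})

#' ITCFit: fitted single-site model with derived Kd
#'
#' @slot params \code{ITCModelParams} point estimates.
#' @slot kdNano numeric dissociation constant in nM (1e9 / Ka).
#' @slot se named numeric approximate standard errors (N, Ka, dH, baseline).
#' @slot residualNorm numeric residual sum of squares (ucal^2).
#' @slot converged logical optimizer convergence.
#' @slot noBinding logical verdict that heats are indistinguishable from a
#'   flat baseline ("NB").
#' @slot message character diagnostic.
#'
#' @exportClass ITCFit
setClass("ITCFit",
  representation(params = "ITCModelParams", kdNano = "numeric",
                 se = "numeric", residualNorm = "numeric",
                 converged = "logical", noBinding = "logical",
                 message = "character"),
  prototype(noBinding = FALSE, message = ""))

#' UnitCell: crystallographic unit cell and symmetry bookkeeping
#'
#' @slot a,b,c numeric cell edges (Angstrom).
#' @slot alpha,beta,gamma numeric cell angles (degrees).
#' @slot spaceGroup character symbol (supported: P1, P2, I2).
#' @slot zAsu integer asymmetric units per cell.
#'
#' @exportClass UnitCell
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric",
                 spaceGroup = "character", zAsu = "integer"))

setValidity("UnitCell", function(object) {
  if (any(c(object@a, object@b, object@c) <= 0))
    return("cell edges must be positive")
  ang <- c(object@alpha, object@beta, object@gamma)
  if (any(ang <= 0 | ang >= 180)) return("cell angles must lie in (0, 180)")
  arg <- 1 - cos(ang[1] * pi / 180)^2 - cos(ang[2] * pi / 180)^2 -
    cos(ang[3] * pi / 180)^2 +
    2 * prod(cos(ang * pi / 180))
  if (arg <= 0) return("cell angles do not define a positive volume")
  TRUE
})
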