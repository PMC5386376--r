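#' Accessors for bh3struct S4 classes
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors atom table of a \code{PDBStructure}.
#' @export
setGeneric("atomRecords", function(x) standardGeneric("atomRecords"))
setMethod("atomRecords", "PDBStructure", function(x) x@atoms)

#' @describeIn accessors chain identifiers present in a structure, in
#'   order of first appearance.
#' @export
setGeneric("chainIDs", function(x) standardGeneric("chainIDs"))
setMethod("chainIDs", "PDBStructure", function(x) unique(x@atoms$chain))

#' @describeIn accessors structure identifier.
#' @export
setGeneric("structureID", function(x) standardGeneric("structureID"))
setMethod("structureID", "PDBStructure", function(x) x@id)

#' @describeIn accessors coordinate matrix.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
setMethod("coords", "CoordSet", function(x) x@coords)
setMethod("coords", "PDBStructure",
          function(x) as.matrix(x@atoms[, c("x", "y", "z")]))

#' @describeIn accessors residue labels of a \code{CoordSet}.
#' @export
setGeneric("residueLabels", function(x) standardGeneric("residueLabels"))
setMethod("residueLabels", "CoordSet", function(x) x@labels)

#' @describeIn accessors 3-letter residue names of a \code{CoordSet}.
#' @export
setGeneric("residueNames", function(x) standardGeneric("residueNames"))
setMethod("residueNames", "CoordSet", function(x) x@resnames)

#' @describeIn accessors RMSD (Angstrom) of a \code{SuperpositionResult}.
#' @export
setGeneric("rmsdValue", function(x) standardGeneric("rmsdValue"))
setMethod("rmsdValue", "SuperpositionResult", function(x) x@rmsd)

#' @describeIn accessors number of paired atoms.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))
setMethod("nPairs", "SuperpositionResult", function(x) x@nPairs)

#' @describeIn accessors 3x3 rotation matrix.
#' @export
setGeneric("rotationMatrix", function(x) standardGeneric("rotationMatrix"))
setMethod("rotationMatrix", "SuperpositionResult", function(x) x@rotation)

#' @describeIn accessors translation vector (Angstrom).
#' @export
setGeneric("translationVector",
           function(x) standardGeneric("translationVector"))
setMethod("translationVector", "SuperpositionResult",
          function(x) x@translation)

#' @describeIn accessors final residue pairing of an iterative alignment.
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))
setMethod("pairTable", "SuperpositionResult", function(x) x@pairs)

#' @describeIn accessors per-atom SASA vector.
#' @export
setGeneric("perAtomArea", function(x) standardGeneric("perAtomArea"))
setMethod("perAtomArea", "SASAResult", function(x) x@perAtom)

#' @describeIn accessors per-residue SASA (named by residue key).
#' @export
setGeneric("perResidueArea", function(x) standardGeneric("perResidueArea"))
setMethod("perResidueArea", "SASAResult", function(x) x@perResidue)

#' @describeIn accessors total SASA.
#' @export
setGeneric("totalArea", function(x) standardGeneric("totalArea"))
setMethod("totalArea", "SASAResult", function(x) x@total)

#' @describeIn accessors total buried SASA of an \code{InterfaceReport}.
#' @export
setGeneric("buriedArea", function(x) standardGeneric("buriedArea"))
setMethod("buriedArea", "InterfaceReport", function(x) x@buriedTotal)

#' @describeIn accessors PISA-convention interface area (buried/2).
#' @export
setGeneric("interfaceArea", function(x) standardGeneric("interfaceArea"))
setMethod("interfaceArea", "InterfaceReport", function(x) x@interfaceArea)

#' @describeIn accessors hydrogen-bond table.
#' @export
setGeneric("hbondTable", function(x) standardGeneric("hbondTable"))
setMethod("hbondTable", "InterfaceReport", function(x) x@hbonds)

#' @describeIn accessors salt-bridge table.
#' @export
setGeneric("saltBridgeTable", function(x) standardGeneric("saltBridgeTable"))
setMethod("saltBridgeTable", "InterfaceReport", function(x) x@saltBridges)

#' @describeIn accessors hot-spot burial table.
#' @export
setGeneric("hotspotTable", function(x) standardGeneric("hotspotTable"))
setMethod("hotspotTable", "InterfaceReport", function(x) x@hotspots)

#' @describeIn accessors per-injection heats (ucal) of an experiment.
#' @export
setGeneric("injectionHeats", function(x) standardGeneric("injectionHeats"))
setMethod("injectionHeats", "ITCExperiment", function(x) x@heats)

#' @describeIn accessors fitted parameters of an \code{ITCFit}.
#' @export
setGeneric("fittedParams", function(x) standardGeneric("fittedParams"))
setMethod("fittedParams", "ITCFit", function(x) x@params)

#' @describeIn accessors dissociation constant in nM.
#' @export
setGeneric("kdNano", function(x) standardGeneric("kdNano"))
setMethod("kdNano", "ITCFit", function(x) x@kdNano)

#' @describeIn accessors whether the fit converged.
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
setMethod("isConverged", "ITCFit", function(x) x@converged)
setMethod("isConverged", "SuperpositionResult", function(x) x@converged)

#' @describeIn accessors no-binding ("NB") verdict of an \code{ITCFit}.
#' @export
setGeneric("isNoBinding", function(x) standardGeneric("isNoBinding"))
setMethod("isNoBinding", "ITCFit", function(x) x@noBinding)

## show methods ---------------------------------------------------------

setMethod("show", "PDBStructure", function(object) {
  a <- object@atoms
  cat("PDBStructure", object@id, "(model", object@model, ")\n")
  cat(" ", nrow(a), "atoms;",
      sum(a$kind == "protein"), "protein /",
      sum(a$kind == "water"), "water /",
      sum(a$kind == "hetero"), "hetero\n")
  if (nrow(a)) cat("  chains:", paste(unique(a$chain), collapse = " "), "\n")
})

setMethod("show", "CoordSet", function(object) {
  cat("CoordSet of", nrow(object@coords), "positions (",
      object@labels[1], "...",
      object@labels[length(object@labels)], ")\n")
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.4f A over %d pairs",
              object@rmsd, object@nPairs))
  if (object@iterations > 0L)
    cat(sprintf(" (%d iterations, %s)", object@iterations,
                if (object@converged) "converged" else "not converged"))
  cat("\n")
})

setMethod("show", "SASAResult", function(object) {
  cat(sprintf("SASAResult: total %.2f A^2 over %d atoms, %d residues\n",
              object@total, length(object@perAtom),
              length(object@perResidue)))
})

setMethod("show", "InterfaceReport", function(object) {
  cat(sprintf(
    "InterfaceReport: buried %.1f A^2 (interface-area convention %.1f)\n",
    object@buriedTotal, object@interfaceArea))
  cat(" ", nrow(object@hbonds), "H-bonds,",
      nrow(object@saltBridges), "salt bridges,",
      nrow(object@hotspots), "hot-spot residues\n")
})

setMethod("show", "ITCExperiment", function(object) {
  cat(sprintf(
    "ITCExperiment: %d x %.1f ul into %.1f ul; cell %.3g M, syringe %.3g M\n",
    length(object@injectionVolumes), object@injectionVolumes[1],
    object@cellVolume, object@cellConc, object@syringeConc))
  if (length(object@heats))
    cat(sprintf("  heats: %.3g .. %.3g ucal\n",
                object@heats[1], object@heats[length(object@heats)]))
})

setMethod("show", "ITCFit", function(object) {
  if (object@noBinding) {
    cat("ITCFit: NB (no binding detected)\n")
  } else {
    p <- object@params
    cat(sprintf(
      "ITCFit: Kd %.1f nM, N %.3f, dH %.0f cal/mol (%s)\n",
      object@kdNano, p@N, p@dH,
      if (object@converged) "converged" else "NOT converged"))
  }
})

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell %s: %.2f %.2f %.2f / %.2f %.2f %.2f (z_asu %d)\n",
              object@spaceGroup, object@a, object@b, object@c,
              object@alpha, object@beta, object@gamma, object@zAsu))
})
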