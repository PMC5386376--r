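# End-to-end runs: structure-based phylogeny, interface report, and an
# ITC binding panel. Each run can write machine-readable artifacts plus
# a JSON manifest (inputs, parameters, seed) so that identical manifests
# imply identical numeric outputs for the deterministic stages.

.writeManifest <- function(path, stage, inputs, params, seed = NULL) {
  jsonlite::write_json(
    list(stage = stage, inputs = inputs, params = params,
         seed = seed, package = "bh3struct",
         version = as.character(utils::packageVersion("bh3struct")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
}

#' Run the structure-based phylogeny analysis
#'
#' Pairwise Calpha RMSD matrix over a structure-mapped alignment,
#' agglomerative clustering, and newick export - the workflow behind
#' structure-based trees of pro-survival Bcl-2 folds.
#'
#' @param msa a \linkS4class{StructureAlignment} (build one with
#'   \code{\link{structureAlignment}}).
#' @param linkage clustering linkage (default "average").
#' @param outPrefix optional path prefix; when given, writes
#'   \code{<prefix>_dist.csv}, \code{<prefix>.nwk} and
#'   \code{<prefix>_manifest.json}.
#' @return list with \code{distances} (matrix), \code{tree}
#'   (\code{hclust}) and \code{newick} (string).
#' @export
runPhylo <- function(msa, linkage = "average", outPrefix = NULL) {
  m <- rmsdMatrix(msa)
  if (max(m) < 1e-6)
    warning("all pairwise distances are (near) zero; ",
            "tree topology is arbitrary", call. = FALSE)
  tree <- clusterStructures(m, linkage = linkage)
  nwk <- toNewick(tree)
  if (!is.null(outPrefix)) {
    utils::write.csv(m, paste0(outPrefix, "_dist.csv"))
    writeLines(nwk, paste0(outPrefix, ".nwk"))
    .writeManifest(paste0(outPrefix, "_manifest.json"), "phylo",
                   list(ids = names(msa@structures)),
                   list(linkage = linkage))
  }
  list(distances = m, tree = tree, newick = nwk)
}

#' Run the full interface analysis of a receptor:peptide complex
#'
#' Buried surface (both conventions), hydrogen bonds, salt bridges and
#' hot-spot burial combined into one report.
#'
#' @param complex a \linkS4class{PDBStructure} or PDB file path.
#' @param receptorChains,peptideChain chain partition.
#' @param hotspots optional peptide residue numbers to profile.
#' @param params a \linkS4class{SASAParams}.
#' @param out optional path prefix; writes \code{<prefix>_report.json},
#'   \code{<prefix>_contacts.csv} and \code{<prefix>_manifest.json}.
#' @param ... further arguments to \code{\link{interfaceReport}}.
#' @return an \linkS4class{InterfaceReport}.
#' @export
runInterface <- function(complex, receptorChains, peptideChain,
                         hotspots = NULL, params = sasaParams(),
                         out = NULL, ...) {
  if (is.character(complex)) complex <- readStructure(complex)
  rep <- interfaceReport(complex, receptorChains, peptideChain,
                         hotspots = hotspots, params = params, ...)
  if (!is.null(out)) {
    jsonlite::write_json(list(
      schema = "bh3struct-interface-1",
      buriedTotal = buriedArea(rep),
      buriedPerPartner = rep@buriedPerPartner,
      interfaceArea = interfaceArea(rep),
      hbonds = hbondTable(rep),
      saltBridges = saltBridgeTable(rep),
      hotspots = hotspotTable(rep)),
      paste0(out, "_report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    contacts <- rbind(
      if (nrow(hbondTable(rep)))
        data.frame(type = "hbond",
                   a = hbondTable(rep)$donor,
                   b = hbondTable(rep)$acceptor,
                   distance = hbondTable(rep)$distance),
      if (nrow(saltBridgeTable(rep)))
        data.frame(type = "salt",
                   a = saltBridgeTable(rep)$basic,
                   b = saltBridgeTable(rep)$acidic,
                   distance = saltBridgeTable(rep)$distance))
    utils::write.csv(contacts %||%
                       data.frame(type = character(0), a = character(0),
                                  b = character(0),
                                  distance = numeric(0)),
                     paste0(out, "_contacts.csv"), row.names = FALSE)
    .writeManifest(paste0(out, "_manifest.json"), "interface",
                   list(structure = structureID(complex)),
                   list(receptor = receptorChains,
                        peptide = peptideChain,
                        probe = params@probeRadius,
                        spherePoints = params@spherePoints))
  }
  rep
}

#' Run an ITC binding panel
#'
#' Fits every replicate of every ligand and aggregates converged binding
#' fits into mean Kd +/- SD; ligands whose replicates all fail or show
#' no binding are reported as "NB" rows, not dropped.
#'
#' @param panel named list; each element is a list of
#'   \linkS4class{ITCExperiment} replicates for one ligand.
#' @param out optional path prefix; writes \code{<prefix>_panel.tsv} and
#'   a manifest.
#' @param ... further arguments to \code{\link{fitSingleSite}}.
#' @return data.frame with one row per ligand: meanKd (nM), sdKd, N
#'   (mean stoichiometry of used fits), nUsed, verdict ("Kd" or "NB").
#' @export
runITCPanel <- function(panel, out = NULL, ...) {
  rows <- lapply(names(panel), function(lig) {
    fits <- lapply(panel[[lig]], fitSingleSite, ...)
    ok <- vapply(fits, function(f) isConverged(f) && !isNoBinding(f),
                 logical(1))
    if (sum(ok) >= 2L) {
      agg <- aggregateReplicates(fits)
      nMean <- mean(vapply(fits[ok],
                           function(f) fittedParams(f)@N, numeric(1)))
      data.frame(ligand = lig, meanKd = agg$meanKd, sdKd = agg$sdKd,
                 N = nMean, nUsed = agg$n, verdict = "Kd")
    } else {
      data.frame(ligand = lig, meanKd = NA_real_, sdKd = NA_real_,
                 N = NA_real_, nUsed = sum(ok), verdict = "NB")
    }
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out)) {
    utils::write.table(tab, paste0(out, "_panel.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    .writeManifest(paste0(out, "_manifest.json"), "itc-panel",
                   list(ligands = names(panel)), list())
  }
  tab
}
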