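#' Construct a structure-mapped multiple sequence alignment
#'
#' The alignment rows must be the gapped sequences of the *modelled*
#' residues of each chain, i.e. ungapping a row must reproduce the
#' one-letter sequence of the Calpha trace of the mapped chain. A
#' structure-guided alignment (e.g. from STRAP or any MSA program run on
#' the modelled sequences) is consumed, not produced, here.
#'
#' @param seqs named character vector of gapped sequences (equal width),
#'   or a path to an aligned FASTA/Clustal file.
#' @param structures named list of \linkS4class{PDBStructure} (names must
#'   be a subset of the alignment ids).
#' @param chains named character vector: chain id per mapped structure.
#' @param format alignment file format when \code{seqs} is a path.
#' @return a \linkS4class{StructureAlignment}.
#' @export
structureAlignment <- function(seqs, structures, chains,
                               format = c("fasta", "clustal")) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs)) {
    format <- match.arg(format)
    msa <- Biostrings::readAAMultipleAlignment(seqs, format = format)
    s <- as.character(msa)
    seqs <- setNames(toupper(s), names(s))
  }
  gsub(".", "-", seqs, fixed = TRUE) -> seqs
  new("StructureAlignment", ids = names(seqs), seqs = seqs,
      structures = structures, chains = chains)
}

#' Equivalent Calpha pairs of two alignment rows
#'
#' Returns the Calpha coordinate pairs for alignment columns where both
#' rows are ungapped and both structures resolve the residue's Calpha.
#'
#' @param msa a \linkS4class{StructureAlignment}.
#' @param idA,idB row identifiers with mapped structures.
#' @return list with \code{a} and \code{b} (paired N x 3 matrices),
#'   \code{labelsA}, \code{labelsB} and \code{columns} (alignment columns
#'   used).
#' @export
equivalentCAPairs <- function(msa, idA, idB) {
  for (id in c(idA, idB))
    .stopIfNot(id %in% names(msa@structures),
               paste0("id '", id, "' has no mapped structure"))
  mapRow <- function(id) {
    cs <- selectCA(msa@structures[[id]], msa@chains[[id]])
    gapped <- strsplit(msa@seqs[[id]], "")[[1]]
    resIdx <- cumsum(gapped != "-")
    obs <- .oneLetter(residueNames(cs))
    n <- max(resIdx)
    if (n != length(obs))
      stop("row '", id, "': alignment has ", n,
           " residues but chain resolves ", length(obs),
           " Calpha atoms; supply an alignment of the modelled sequences",
           call. = FALSE)
    letters <- strsplit(toupper(paste(gapped[gapped != "-"],
                                      collapse = "")), "")[[1]]
    mism <- sum(letters != obs & letters != "X" & obs != "X")
    if (mism > 0)
      warning("row '", id, "': ", mism,
              " residue letter(s) disagree with the structure", call. = FALSE)
    list(cs = cs, gapped = gapped, resIdx = resIdx)
  }
  ra <- mapRow(idA); rb <- mapRow(idB)
  both <- ra$gapped != "-" & rb$gapped != "-"
  cols <- which(both)
  if (length(cols) < 3L)
    stop("insufficient overlap: fewer than 3 shared alignment columns",
         call. = FALSE)
  ia <- ra$resIdx[cols]; ib <- rb$resIdx[cols]
  list(a = coords(ra$cs)[ia, , drop = FALSE],
       b = coords(rb$cs)[ib, , drop = FALSE],
       labelsA = residueLabels(ra$cs)[ia],
       labelsB = residueLabels(rb$cs)[ib],
       columns = cols)
}

#' Pairwise Calpha RMSD distance matrix from a structure alignment
#'
#' Entry (a, b) is the Kabsch RMSD over the equivalent Calpha pairs of
#' rows a and b; each pair is superposed independently (no common
#' reference frame). The matrix is symmetric with a zero diagonal.
#'
#' @param msa a \linkS4class{StructureAlignment} with >= 2 mapped
#'   structures.
#' @param onMissing what to do when a pair has insufficient overlap:
#'   \code{"error"} (default) or \code{"na"}.
#' @return symmetric numeric matrix (Angstrom) with id dimnames.
#' @export
rmsdMatrix <- function(msa, onMissing = c("error", "na")) {
  onMissing <- match.arg(onMissing)
  ids <- names(msa@structures)
  .stopIfNot(length(ids) >= 2L, "need at least 2 mapped structures")
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    pr <- tryCatch(equivalentCAPairs(msa, ids[i], ids[j]),
                   error = function(e)
                     if (onMissing == "na" &&
                         grepl("insufficient overlap", conditionMessage(e)))
                       NULL else stop(e))
    v <- if (is.null(pr)) NA_real_ else rmsdValue(kabsch(pr$b, pr$a))
    m[i, j] <- m[j, i] <- v
  }
  m
}

#' Agglomerative clustering of a structural distance matrix
#'
#' @param matrix symmetric distance matrix (zero diagonal), e.g. from
#'   \code{\link{rmsdMatrix}}.
#' @param linkage one of \code{"average"} (UPGMA, default),
#'   \code{"single"}, \code{"complete"}, \code{"ward.D2"}.
#' @return an object of class \code{hclust}; merge heights are in the
#'   units of the input matrix (Angstrom for RMSD matrices).
#' @export
clusterStructures <- function(matrix,
                              linkage = c("average", "single",
                                          "complete", "ward.D2")) {
  linkage <- match.arg(linkage)
  .stopIfNot(is.matrix(matrix) && nrow(matrix) == ncol(matrix),
             "input must be a square matrix")
  if (any(is.na(matrix)))
    stop("distance matrix has missing entries; resolve them first",
         call. = FALSE)
  if (max(abs(matrix - t(matrix))) > 1e-9)
    stop("distance matrix is not symmetric within 1e-9", call. = FALSE)
  if (max(abs(diag(matrix))) > 1e-9)
    stop("distance matrix diagonal is not zero", call. = FALSE)
  stats::hclust(stats::as.dist(matrix), method = linkage)
}

#' Newick export of a dendrogram
#'
#' Branch lengths follow the ultrametric convention: each leaf sits at
#' depth height/2 below its merge node, so the toy matrix
#' d(A,B)=2, d(A,C)=d(B,C)=6 yields \code{((A:1,B:1):2,C:3);} under
#' average linkage.
#'
#' @param tree an \code{hclust} object (or a single leaf label for the
#'   degenerate one-structure case).
#' @return single newick string, terminated by ";".
#' @export
toNewick <- function(tree) {
  if (is.character(tree) && length(tree) == 1L)
    return(paste0(tree, ";"))
  .stopIfNot(inherits(tree, "hclust"), "tree must be an hclust object")
  ape::write.tree(ape::as.phylo(tree))
}
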