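#' Kabsch rigid-body superposition
#'
#' Least-squares superposition of a moving coordinate set onto a fixed one
#' via the SVD of the cross-covariance matrix, with the proper-rotation
#' correction for reflection-requiring degenerate cases (the sign of the
#' smallest-singular-value axis is flipped so det(R) = +1). The returned
#' RMSD is computed after applying the optimal transform.
#'
#' @param moving,fixed \linkS4class{CoordSet}s or N x 3 matrices with equal
#'   row counts (N >= 3).
#' @return a \linkS4class{SuperpositionResult}; the transform maps
#'   \code{moving} onto \code{fixed} as \code{x' = R x + t}.
#' @examples
#' a <- coords(selectCA(makeHelix(20), "A"))
#' b <- a %*% t(rotationZ(90)) + rep(1, 3)
#' rmsdValue(kabsch(b, a))  # ~0
#' @export
kabsch <- function(moving, fixed) {
  P <- if (is(moving, "CoordSet")) coords(moving) else as.matrix(moving)
  Q <- if (is(fixed, "CoordSet")) coords(fixed) else as.matrix(fixed)
  .stopIfNot(nrow(P) == nrow(Q),
             "coordinate sets must have equal row counts")
  .stopIfNot(nrow(P) >= 3L,
             "under-determined: need at least 3 atom pairs")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))            # t(Pc) %*% Qc = U D V'
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cq - R %*% cp)
  dev <- Pc %*% t(R) - Qc
  rmsd <- sqrt(mean(rowSums(dev^2)))
  new("SuperpositionResult", rotation = R, translation = tr,
      rmsd = rmsd, nPairs = nrow(P))
}

#' Apply a superposition transform to coordinates
#'
#' @param x N x 3 matrix, \linkS4class{CoordSet} or
#'   \linkS4class{PDBStructure}.
#' @param result a \linkS4class{SuperpositionResult}.
#' @return object of the same type with transformed coordinates.
#' @export
applyTransform <- function(x, result) {
  R <- rotationMatrix(result); tr <- translationVector(result)
  if (is(x, "PDBStructure")) {
    a <- atomRecords(x)
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
    a$x <- xyz[, 1] + tr[1]; a$y <- xyz[, 2] + tr[2]; a$z <- xyz[, 3] + tr[3]
    return(initialize(x, atoms = a))
  }
  if (is(x, "CoordSet")) {
    m <- sweep(coords(x) %*% t(R), 2, tr, "+")
    return(initialize(x, coords = m))
  }
  sweep(as.matrix(x) %*% t(R), 2, tr, "+")
}

#' Rotation matrix about the z axis
#'
#' @param degrees rotation angle.
#' @return 3 x 3 rotation matrix.
#' @export
rotationZ <- function(degrees) {
  th <- degrees * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

#' Random proper rotation (uniform over SO(3))
#'
#' Quaternion sampling; used by property tests and fixtures.
#'
#' @param seed optional integer seed.
#' @return 3 x 3 rotation matrix with det +1.
#' @export
randomRotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

#' Sequence-independent iterative structural alignment
#'
#' Aligns one chain onto another without assuming a shared numbering:
#' a correspondence seed is taken from a global sequence alignment of the
#' two chains (BLOSUM62), falling back to the best gapless sliding-window
#' seed when the sequences are too dissimilar; the algorithm then
#' alternates Kabsch superposition with re-pairing of mutually nearest
#' Calpha atoms within a distance cutoff until the pair set is stable.
#' This approximates what structure-comparison servers do when reporting
#' an RMSD "over N Calpha atoms", without any claim of reproducing their
#' scores.
#'
#' @param a,b \linkS4class{PDBStructure}s (fixed and moving).
#' @param chainA,chainB chain ids.
#' @param cutoff re-pairing distance cutoff in Angstrom (default 4.5).
#' @param maxIter maximum refinement iterations (default 50).
#' @param minSeedIdentity percent identity below which the sliding-window
#'   seed replaces the sequence-alignment seed (default 20).
#' @return a \linkS4class{SuperpositionResult} whose \code{pairs} slot
#'   lists the final residue correspondence with per-pair distances.
#' @export
alignStructures <- function(a, chainA, b, chainB, cutoff = 4.5,
                            maxIter = 50L, minSeedIdentity = 20) {
  csA <- selectCA(a, chainA)
  csB <- selectCA(b, chainB)
  .stopIfNot(nrow(coords(csA)) >= 20L && nrow(coords(csB)) >= 20L,
             "both chains must have at least 20 Calpha atoms")
  seed <- .seedPairs(csA, csB, minSeedIdentity)
  if (nrow(seed) < 3L)
    stop("alignment failure: no seed correspondence found", call. = FALSE)

  A <- coords(csA); B <- coords(csB)
  pairs <- seed
  fit <- NULL
  converged <- FALSE
  iter <- 0L
  history <- character(0)
  while (iter < maxIter) {
    iter <- iter + 1L
    fit <- kabsch(B[pairs$ib, , drop = FALSE], A[pairs$ia, , drop = FALSE])
    Bt <- applyTransform(B, fit)
    newPairs <- .mutualNearest(A, Bt, cutoff)
    if (nrow(newPairs) < 3L)
      stop("alignment failure: fewer than 3 pairs within cutoff",
           call. = FALSE)
    sig <- paste(newPairs$ia, newPairs$ib, collapse = ";")
    if (identical(sig, paste(pairs$ia, pairs$ib, collapse = ";"))) {
      converged <- TRUE
      pairs <- newPairs
      break
    }
    if (sig %in% history) {            # oscillating pair set
      pairs <- newPairs
      break
    }
    history <- c(history, sig)
    pairs <- newPairs
  }
  if (!converged)
    warning("pair set did not stabilise within ", iter,
            " iterations; reporting the last state", call. = FALSE)
  fit <- kabsch(B[pairs$ib, , drop = FALSE], A[pairs$ia, , drop = FALSE])
  Bt <- applyTransform(B, fit)
  d <- sqrt(rowSums((A[pairs$ia, , drop = FALSE] -
                     Bt[pairs$ib, , drop = FALSE])^2))
  pairTab <- data.frame(
    labelA = residueLabels(csA)[pairs$ia],
    labelB = residueLabels(csB)[pairs$ib],
    distance = d, stringsAsFactors = FALSE)
  initialize(fit, pairs = pairTab, iterations = iter, converged = converged)
}

# correspondence seed: global sequence alignment, or best gapless window
.seedPairs <- function(csA, csB, minSeedIdentity) {
  sA <- paste(.oneLetter(residueNames(csA)), collapse = "")
  sB <- paste(.oneLetter(residueNames(csB)), collapse = "")
  al <- tryCatch(
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(sA), Biostrings::AAString(sB),
      substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5, type = "global"),
    error = function(e) NULL)
  if (!is.null(al) && Biostrings::pid(al) >= minSeedIdentity) {
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ia <- cumsum(pa != "-"); ib <- cumsum(pb != "-")
    keep <- pa != "-" & pb != "-"
    return(data.frame(ia = ia[keep], ib = ib[keep]))
  }
  .slidingSeed(coords(csA), coords(csB))
}

# gapless sliding-window seed: the offset whose index-shifted pairing
# gives the lowest Kabsch RMSD
.slidingSeed <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  best <- NULL; bestRmsd <- Inf
  for (off in seq(-(nB - 20L), nA - 20L)) {
    ia <- pmax(1L, 1L + off):pmin(nA, nB + off)
    ib <- ia - off
    if (length(ia) < 20L) next
    r <- rmsdValue(kabsch(B[ib, , drop = FALSE], A[ia, , drop = FALSE]))
    if (r < bestRmsd) { bestRmsd <- r; best <- data.frame(ia = ia, ib = ib) }
  }
  if (is.null(best)) data.frame(ia = integer(0), ib = integer(0)) else best
}

# mutually nearest neighbour pairs within cutoff, ordered by the smaller
# residue index first (deterministic tie-break)
.mutualNearest <- function(A, B, cutoff) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  jOfI <- max.col(-d2, ties.method = "first")
  iOfJ <- max.col(-t(d2), ties.method = "first")
  ia <- seq_len(nrow(A))
  mutual <- iOfJ[jOfI] == ia & d2[cbind(ia, jOfI)] <= cutoff^2
  out <- data.frame(ia = ia[mutual], ib = jOfI[mutual])
  out[order(out$ia), , drop = FALSE]
}
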