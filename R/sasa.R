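#' Shrake-Rupley quadrature parameters
#'
#' @param probeRadius solvent probe radius in Angstrom (default 1.4, a
#'   water-sized probe).
#' @param spherePoints number of quadrature points per atom sphere
#'   (default 960).
#' @return a \linkS4class{SASAParams}.
#' @export
sasaParams <- function(probeRadius = 1.4, spherePoints = 960L) {
  new("SASAParams", probeRadius = probeRadius,
      spherePoints = as.integer(spherePoints))
}

# golden-section spiral: near-uniform deterministic points on the unit
# sphere, in a canonical orientation
.goldenSpiral <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# rotation-covariant molecular frame: an orthonormal basis built by
# Gram-Schmidt from vectors between intrinsic reference atoms (first to
# last, first to an interior atom chosen for non-collinearity). The
# frame is a pure function of the coordinates and rotates exactly with
# the molecule, so quadrature results are rigid-motion invariant by
# construction. Collinear or tiny inputs fall back to the identity.
.molecularFrame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 3L) return(diag(3))
  u1 <- xyz[n, ] - xyz[1, ]
  l1 <- sqrt(sum(u1^2))
  if (l1 < 1e-6) return(diag(3))
  u1 <- u1 / l1
  for (k in unique(c(max(2L, n %/% 2L), seq_len(n)))) {
    v <- xyz[k, ] - xyz[1, ]
    v <- v - sum(v * u1) * u1
    l2 <- sqrt(sum(v^2))
    if (l2 > 1e-6 * max(l1, 1)) {
      u2 <- v / l2
      u3 <- c(u1[2] * u2[3] - u1[3] * u2[2],
              u1[3] * u2[1] - u1[1] * u2[3],
              u1[1] * u2[2] - u1[2] * u2[1])
      return(cbind(u1, u2, u3))
    }
  }
  diag(3)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA by test points on each atom's solvent-expanded sphere:
#' per-atom area = (accessible point fraction) x 4 pi (r + probe)^2.
#' The quadrature point set is a golden-section spiral expressed in a
#' molecule-intrinsic frame, so results are invariant under rigid motion
#' of the input. Waters and heteroatoms are excluded by default;
#' hydrogens are always excluded.
#'
#' @param structure a \linkS4class{PDBStructure}, or an atom data.frame.
#' @param params a \linkS4class{SASAParams}.
#' @param includeHetero include non-water heteroatoms (default FALSE).
#' @param frame optional 3 x 3 quadrature orientation. Difference-based
#'   quantities (buried areas, burial fractions) must evaluate all their
#'   SASA terms in one common frame so that quadrature error cancels
#'   exactly; \code{\link{buriedSurface}} and friends pass the frame of
#'   the full complex here. Defaults to the molecule-intrinsic frame of
#'   \code{structure}.
#' @return a \linkS4class{SASAResult}.
#' @examples
#' h <- makeHelix(10, sidechains = TRUE)
#' totalArea(sasa(h))
#' @export
sasa <- function(structure, params = sasaParams(), includeHetero = FALSE,
                 frame = NULL) {
  atoms <- if (is(structure, "PDBStructure")) atomRecords(structure)
           else structure
  keepKind <- if (includeHetero) c("protein", "hetero") else "protein"
  atoms <- atoms[atoms$kind %in% keepKind &
                 toupper(atoms$element) != "H", , drop = FALSE]
  .stopIfNot(nrow(atoms) > 0L, "no atoms with known radii to analyse")
  radii <- atomRadii(atoms)
  if (any(radii <= 0))
    stop("unknown radius for atom ",
         paste(atoms$name[radii <= 0][1], atoms$resname[radii <= 0][1]),
         call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  probe <- params@probeRadius
  if (is.null(frame)) frame <- .molecularFrame(xyz)
  S0 <- .goldenSpiral(params@spherePoints) %*% t(frame)

  n <- nrow(xyz)
  R <- radii + probe
  area <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    di2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
           (xyz[, 3] - xyz[i, 3])^2
    nb <- which(di2 < (R[i] + maxR)^2 & di2 > 1e-12)
    nb <- nb[di2[nb] < (R[i] + R[nb])^2]
    pts <- sweep(S0 * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(pts))
    for (j in nb) {
      if (!any(acc)) break
      w <- which(acc)
      dj2 <- (pts[w, 1] - xyz[j, 1])^2 + (pts[w, 2] - xyz[j, 2])^2 +
             (pts[w, 3] - xyz[j, 3])^2
      acc[w[dj2 < R[j]^2]] <- FALSE
    }
    area[i] <- mean(acc) * 4 * pi * R[i]^2
  }
  keys <- .residueKey(atoms)
  perRes <- tapply(area, keys, sum)
  perRes <- setNames(as.numeric(perRes), names(perRes))
  new("SASAResult", perAtom = area, perResidue = perRes,
      total = sum(area), atomKeys = keys)
}

#' Buried surface area of a two-body complex
#'
#' Computes SASA of each partner in isolation (at complex coordinates)
#' and of the assembled complex; the buried total is
#' SASA(A) + SASA(B) - SASA(AB). Both common conventions are reported:
#' the total and its half (PISA-style "interface area"), since published
#' buried-surface figures use either.
#'
#' @param complex a \linkS4class{PDBStructure} containing both partners.
#' @param partA,partB disjoint character vectors of chain ids.
#' @param params a \linkS4class{SASAParams}.
#' @return an \linkS4class{InterfaceReport} with the buried-area fields
#'   filled in (contact tables empty).
#' @export
buriedSurface <- function(complex, partA, partB, params = sasaParams()) {
  .stopIfNot(length(intersect(partA, partB)) == 0L,
             "partner chain sets must be disjoint")
  avail <- chainIDs(complex)
  miss <- setdiff(c(partA, partB), avail)
  .stopIfNot(length(miss) == 0L,
             paste("chain(s) not in complex:", paste(miss, collapse = ", ")))
  a <- atomRecords(complex)
  a <- a[a$kind == "protein", , drop = FALSE]
  inA <- a$chain %in% partA
  inB <- a$chain %in% partB
  # one quadrature frame for all three terms: quadrature error cancels
  # in the difference, so well-separated chains bury exactly zero
  fr <- .molecularFrame(as.matrix(a[inA | inB, c("x", "y", "z")]))
  sA <- sasa(a[inA, , drop = FALSE], params, frame = fr)
  sB <- sasa(a[inB, , drop = FALSE], params, frame = fr)
  sAB <- sasa(a[inA | inB, , drop = FALSE], params, frame = fr)
  whichA <- which(a$chain[inA | inB] %in% partA)
  whichB <- which(a$chain[inA | inB] %in% partB)
  buriedA <- sum(perAtomArea(sA)) - sum(perAtomArea(sAB)[whichA])
  buriedB <- sum(perAtomArea(sB)) - sum(perAtomArea(sAB)[whichB])
  total <- totalArea(sA) + totalArea(sB) - totalArea(sAB)
  new("InterfaceReport",
      buriedTotal = total,
      buriedPerPartner = c(buriedA, buriedB),
      interfaceArea = total / 2)
}
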