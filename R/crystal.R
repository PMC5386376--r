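# Unit-cell arithmetic: volume, Matthews coefficient / solvent content,
# and unique-reflection counting for the supported space groups.

#' Construct a unit cell
#'
#' @param a,b,c cell edges in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @param spaceGroup symbol; supported for reflection counting: P1, P2,
#'   I2 (monoclinic, b unique).
#' @param zAsu asymmetric units per cell; defaults to the general
#'   position count of the space group (P1: 1, P2: 2, I2: 4).
#' @return a \linkS4class{UnitCell}.
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                     spaceGroup = "P1", zAsu = NULL) {
  if (is.null(zAsu))
    zAsu <- switch(toupper(spaceGroup), P1 = 1L, P2 = 2L, I2 = 4L,
                   C2 = 4L, 1L)
  new("UnitCell", a = a, b = b, c = c, alpha = alpha, beta = beta,
      gamma = gamma, spaceGroup = toupper(spaceGroup),
      zAsu = as.integer(zAsu))
}

#' Unit-cell volume
#'
#' General triclinic formula
#' V = abc sqrt(1 - cos^2 a - cos^2 b - cos^2 g + 2 cos a cos b cos g);
#' for a monoclinic cell this reduces to a b c sin(beta).
#'
#' @param cell a \linkS4class{UnitCell}.
#' @return volume in Angstrom^3.
#' @export
cellVolume <- function(cell) {
  ca <- cos(cell@alpha * pi / 180)
  cb <- cos(cell@beta * pi / 180)
  cg <- cos(cell@gamma * pi / 180)
  cell@a * cell@b * cell@c *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

#' Protein molecular weight from sequence
#'
#' Average (not monoisotopic) residue masses summed over the chain, plus
#' one water per chain for the termini.
#'
#' @param sequence one-letter amino-acid string, or an integer residue
#'   count (then the mean residue mass 110 Da is used).
#' @return molecular weight in Da.
#' @export
proteinMW <- function(sequence) {
  if (is.numeric(sequence))
    return(sequence * 110 + .WATER_MASS)
  chars <- strsplit(toupper(sequence), "")[[1]]
  m <- .RESIDUE_MASS[chars]
  if (any(is.na(m)))
    stop("unknown residue(s): ",
         paste(unique(chars[is.na(m)]), collapse = ", "), call. = FALSE)
  sum(m) + .WATER_MASS
}

#' Matthews coefficient and solvent content
#'
#' Vm = V / (z_asu * MW_asu); solvent fraction = 1 - 1.23/Vm with the
#' standard 1.23 Da/A^3 protein density convention.
#'
#' @param cell a \linkS4class{UnitCell}.
#' @param mwAsu total molecular weight of the asymmetric unit (Da), or a
#'   list/vector of one-letter chain sequences to sum via
#'   \code{\link{proteinMW}}.
#' @return list with \code{matthews} (A^3/Da), \code{solventPercent} and
#'   \code{plausible} (FALSE when Vm <= 1.23, i.e. more protein than
#'   fits the cell).
#' @export
solventContent <- function(cell, mwAsu) {
  if (!is.numeric(mwAsu))
    mwAsu <- sum(vapply(mwAsu, proteinMW, numeric(1)))
  .stopIfNot(mwAsu > 0, "asymmetric-unit molecular weight must be > 0")
  vm <- cellVolume(cell) / (cell@zAsu * mwAsu)
  list(matthews = vm,
       solventPercent = 100 * (1 - 1.23 / vm),
       plausible = vm > 1.23)
}

# symmetry mates of (h,k,l) under the Laue group, Friedel included
.laueOps <- function(spaceGroup) {
  base <- switch(spaceGroup,
    P1 = list(c(1, 1, 1)),
    P2 = ,
    C2 = ,
    I2 = list(c(1, 1, 1), c(-1, 1, -1)),   # 2/m, b unique
    stop("unsupported space group for reflection counting: ",
         spaceGroup, call. = FALSE))
  c(base, lapply(base, function(s) -s))    # Friedel mates
}

#' Count unique reflections in a resolution range
#'
#' Enumerates integer (h, k, l) with d_max >= d(hkl) >= d_min using the
#' general triclinic reciprocal metric, removes centring-extinct
#' reflections (h+k+l odd for I lattices), merges each Laue-group orbit
#' (Friedel pairs included) to one representative, excludes (0,0,0) and
#' scales by the completeness.
#'
#' @param cell a \linkS4class{UnitCell}.
#' @param dMin high-resolution limit (Angstrom).
#' @param dMax low-resolution limit (Angstrom, default Inf).
#' @param completeness fraction of the unique set observed (default 1).
#' @param canonical orbit representative rule, \code{"min"} or
#'   \code{"max"} lexicographic; the count must not depend on it.
#' @return expected number of unique reflections (rounded).
#' @export
countUniqueReflections <- function(cell, dMin, dMax = Inf,
                                   completeness = 1,
                                   canonical = c("min", "max")) {
  canonical <- match.arg(canonical)
  .stopIfNot(dMin > 0 && dMin < dMax, "need 0 < dMin < dMax")
  sg <- cell@spaceGroup
  ops <- .laueOps(sg)

  d2r <- pi / 180
  ca <- cos(cell@alpha * d2r); cb <- cos(cell@beta * d2r)
  cg <- cos(cell@gamma * d2r)
  sa <- sin(cell@alpha * d2r); sb <- sin(cell@beta * d2r)
  sg_ <- sin(cell@gamma * d2r)
  V <- cellVolume(cell)
  as_ <- cell@b * cell@c * sa / V
  bs <- cell@a * cell@c * sb / V
  cs <- cell@a * cell@b * sg_ / V
  cas <- (cb * cg - ca) / (sb * sg_)
  cbs <- (ca * cg - cb) / (sa * sg_)
  cgs <- (ca * cb - cg) / (sa * sb)

  hmax <- ceiling(cell@a / dMin) + 1L
  kmax <- ceiling(cell@b / dMin) + 1L
  lmax <- ceiling(cell@c / dMin) + 1L
  g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  invd2 <- g$h^2 * as_^2 + g$k^2 * bs^2 + g$l^2 * cs^2 +
    2 * g$k * g$l * bs * cs * cas +
    2 * g$h * g$l * as_ * cs * cbs +
    2 * g$h * g$k * as_ * bs * cgs
  d <- suppressWarnings(1 / sqrt(invd2))
  keep <- is.finite(d) & d >= dMin & d <= dMax &
    !(g$h == 0 & g$k == 0 & g$l == 0)
  if (startsWith(sg, "I")) keep <- keep & (g$h + g$k + g$l) %% 2 == 0
  if (startsWith(sg, "C")) keep <- keep & (g$h + g$k) %% 2 == 0
  g <- g[keep, , drop = FALSE]
  if (!nrow(g)) return(0L)

  # orbit key: lexicographic extreme over symmetry/Friedel mates, via an
  # injective integer encoding of each mate
  M <- 2L * max(hmax, kmax, lmax) + 3L
  enc <- function(h, k, l) ((h + M) * (2 * M) + (k + M)) * (2 * M) + (l + M)
  keys <- vapply(ops, function(s)
    enc(g$h * s[1], g$k * s[2], g$l * s[3]), numeric(nrow(g)))
  keys <- matrix(keys, nrow = nrow(g))
  key <- if (canonical == "min") do.call(pmin, as.data.frame(keys))
         else do.call(pmax, as.data.frame(keys))
  round(length(unique(key)) * completeness)
}
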