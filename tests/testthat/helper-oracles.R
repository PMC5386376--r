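# Independent oracles used across the suite. These deliberately share no
# code with the implementation they check.

# Horn's quaternion method for optimal-superposition RMSD: the largest
# eigenvalue of the 4x4 key matrix gives the residual in closed form.
quaternionRMSD <- function(moving, fixed) {
  X <- sweep(moving, 2, colMeans(moving))
  Y <- sweep(fixed, 2, colMeans(fixed))
  S <- t(X) %*% Y
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(X^2) + sum(Y^2) - 2 * lam)) / nrow(X))
}

# closed-form accessible area of each of two equal spheres of expanded
# radius R whose centres are d apart (d < 2R): full sphere minus the
# spherical cap of height h = R - d/2 swallowed by the neighbour.
twoSphereAccessible <- function(R, d) {
  h <- R - d / 2
  4 * pi * R^2 - 2 * pi * R * h
}

# exhaustive Friedel-merged reflection count for a P1 cell: enumerate
# every (h,k,l) in range and keep the standard hemisphere
# (l > 0, or l = 0 & k > 0, or l = k = 0 & h > 0).
bruteForceP1Count <- function(a, b, c, alpha, beta, gamma, dMin,
                              dMax = Inf) {
  d2r <- pi / 180
  ca <- cos(alpha * d2r); cb <- cos(beta * d2r); cg <- cos(gamma * d2r)
  V <- a * b * c * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  as_ <- b * c * sin(alpha * d2r) / V
  bs <- a * c * sin(beta * d2r) / V
  cs <- a * b * sin(gamma * d2r) / V
  cas <- (cb * cg - ca) / (sin(beta * d2r) * sin(gamma * d2r))
  cbs <- (ca * cg - cb) / (sin(alpha * d2r) * sin(gamma * d2r))
  cgs <- (ca * cb - cg) / (sin(alpha * d2r) * sin(beta * d2r))
  hm <- ceiling(a / dMin) + 2L; km <- ceiling(b / dMin) + 2L
  lm <- ceiling(c / dMin) + 2L
  count <- 0L
  for (h in -hm:hm) for (k in -km:km) for (l in -lm:lm) {
    if (h == 0 && k == 0 && l == 0) next
    hemi <- l > 0 || (l == 0 && k > 0) || (l == 0 && k == 0 && h > 0)
    if (!hemi) next
    invd2 <- h^2 * as_^2 + k^2 * bs^2 + l^2 * cs^2 +
      2 * k * l * bs * cs * cas + 2 * h * l * as_ * cs * cbs +
      2 * h * k * as_ * bs * cgs
    d <- 1 / sqrt(invd2)
    if (d >= dMin && d <= dMax) count <- count + 1L
  }
  count
}

# text of a tiny hand-written PDB file (used for parser edge cases)
writeFixturePDB <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdbAtomLine <- function(serial, name, resname, chain, resseq, x, y, z,
                        occ = 1.00, bfac = 0.00, altloc = " ",
                        element = "", record = "ATOM") {
  padName <- if (nchar(name) <= 3) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, padName, altloc, resname, chain, resseq,
          x, y, z, occ, bfac, element)
}

# helix CA coordinates without going through the generator under test
idealHelixCoords <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  th <- (seq_len(n) - 1) * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), (seq_len(n) - 1) * rise)
}
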