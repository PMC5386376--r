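singleAtom <- function(name = "CB", resname = "ALA", x = 0, y = 0, z = 0,
                       chain = "A", resseq = 1L) {
  data.frame(name = name, resname = resname, chain = chain,
             resseq = resseq, x = x, y = y, z = z)
}

test_that("a lone atom recovers the analytic sphere area", {
  s <- sasa(newStructure(singleAtom()))          # aliphatic C, r = 1.87
  analytic <- 4 * pi * (1.87 + 1.4)^2
  expect_equal(totalArea(s), analytic, tolerance = 5e-3)
  # quadrature of an unoccluded sphere is in fact exact
  expect_equal(totalArea(s), analytic, tolerance = 1e-12)
})

test_that("well-separated atoms are additive", {
  two <- rbind(singleAtom(), singleAtom(x = 20, resseq = 2L))
  s <- sasa(newStructure(two))
  expect_equal(totalArea(s), 2 * 4 * pi * 3.27^2, tolerance = 1e-12)
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  two <- rbind(singleAtom(), singleAtom(x = 3.0, resseq = 2L))
  s <- sasa(newStructure(two))
  R <- 1.87 + 1.4
  expected <- twoSphereAccessible(R, 3.0)
  expect_equal(perAtomArea(s)[1], expected, tolerance = 5e-3 * expected)
  expect_equal(perAtomArea(s)[2], expected, tolerance = 5e-3 * expected)
})

test_that("quadrature converges: doubling the points moves totals <0.3%", {
  h <- makeHelix(15, sequence = "ASDVLFGKREWTYMN", sidechains = TRUE)
  t1 <- totalArea(sasa(h, sasaParams(spherePoints = 960)))
  t2 <- totalArea(sasa(h, sasaParams(spherePoints = 1920)))
  expect_lt(abs(t2 - t1) / t1, 0.003)
})

test_that("per-residue areas sum to the per-atom total", {
  h <- makeHelix(10, sequence = "ASDVLFGKRE", sidechains = TRUE)
  s <- sasa(h)
  expect_equal(sum(perResidueArea(s)), sum(perAtomArea(s)),
               tolerance = 1e-9)
  expect_equal(totalArea(s), sum(perAtomArea(s)), tolerance = 1e-9)
})

test_that("SASA is invariant under rigid motion of the structure", {
  h <- makeHelix(12, sequence = "ASDVLFGKREWT", sidechains = TRUE)
  base <- totalArea(sasa(h))
  for (seed in 1:3) {
    moved <- rigidMove(h, randomRotation(seed), c(10, -5, 3) * seed)
    expect_equal(totalArea(sasa(moved)), base, tolerance = 1e-6)
  }
})

test_that("buried surface vanishes for distant chains and is symmetric", {
  g <- makeGrooveComplex("GSVAGLSAFDGVAGS")     # peptide only
  far <- atomRecords(makeHelix(10, chain = "C", sidechains = TRUE))
  far$x <- far$x + 50
  cplx <- newStructure(rbind(
    atomRecords(g$structure)[, c("name", "resname", "chain", "resseq",
                                 "x", "y", "z")],
    far[, c("name", "resname", "chain", "resseq", "x", "y", "z")]))
  rep <- buriedSurface(cplx, "B", "C")
  expect_equal(buriedArea(rep), 0, tolerance = 1e-9)
  # symmetry in the partner sets for a touching complex
  g2 <- makeGrooveComplex("GSVAGLSAFDGVAGS",
                          plan = list(list(type = "hbond", peptideRes = 7)))
  r1 <- buriedSurface(g2$structure, "A", "B")
  r2 <- buriedSurface(g2$structure, "B", "A")
  expect_equal(buriedArea(r1), buriedArea(r2), tolerance = 1e-9)
  expect_gt(buriedArea(r1), 0)
  expect_equal(interfaceArea(r1), buriedArea(r1) / 2)
  expect_error(buriedSurface(g2$structure, "A", "A"), "disjoint")
})

test_that("buried total equals an independent per-atom recomputation", {
  g <- makeGrooveComplex("GSVAGLSAFDGVAGS", plan = list(
    list(type = "hbond", peptideRes = 7, dist = 2.9),
    list(type = "salt", peptideRes = 10, dist = 3.2)))
  cplx <- g$structure
  rep <- buriedSurface(cplx, "A", "B")
  # definitional oracle: recompute the three SASA terms atom by atom in
  # the shared quadrature frame of the full complex
  a <- atomRecords(cplx)
  fr <- bh3struct:::.molecularFrame(as.matrix(a[, c("x", "y", "z")]))
  sA <- sasa(a[a$chain == "A", , drop = FALSE], frame = fr)
  sB <- sasa(a[a$chain == "B", , drop = FALSE], frame = fr)
  sAB <- sasa(a, frame = fr)
  oracle <- sum(perAtomArea(sA)) + sum(perAtomArea(sB)) -
    sum(perAtomArea(sAB))
  expect_equal(buriedArea(rep), oracle, tolerance = 1e-6)
  expect_equal(sum(rep@buriedPerPartner), buriedArea(rep),
               tolerance = 1e-6)
})

test_that("hydrogen bonds obey the distance and angle criteria", {
  near <- makeGrooveComplex("GSVAGLSAFDGVAGS",
                            plan = list(list(type = "hbond",
                                             peptideRes = 7, dist = 2.9)))
  hb <- findHBonds(near$structure, "A", "B")
  expect_true(any(grepl("SER7:OG", hb$donor) &
                  grepl("GLU1:OE1", hb$acceptor)))
  expect_true(all(hb$distance <= 3.5))
  expect_true(all(is.na(hb$angle) | hb$angle >= 90))
  # same geometry at 5.0 A: nothing across the interface
  farP <- makeGrooveComplex("GSVAGLSAFDGVAGS",
                            plan = list(list(type = "hbond",
                                             peptideRes = 7, dist = 5.0)))
  hb2 <- findHBonds(farP$structure, "A", "B")
  expect_false(any(grepl("SER7:OG", hb2$donor)))
})

test_that("salt bridges obey the distance criterion", {
  g <- makeGrooveComplex("GSVAGLSAFDGVAGS",
                         plan = list(list(type = "salt",
                                          peptideRes = 10, dist = 3.2)))
  sb <- findSaltBridges(g$structure, "A", "B")
  expect_true(any(grepl("ARG", sb$basicResidue) &
                  grepl("ASP10", sb$acidicResidue)))
  expect_true(all(sb$distance <= 4.0))
  far <- makeGrooveComplex("GSVAGLSAFDGVAGS",
                           plan = list(list(type = "salt",
                                            peptideRes = 10, dist = 6.0)))
  expect_equal(nrow(findSaltBridges(far$structure, "A", "B")), 0L)
})

test_that("hot-spot burial separates enclosed from free side chains", {
  pepOnly <- makeGrooveComplex("GSVAGLSAFDGVAGS")
  hsFree <- hotspotBurial(pepOnly$structure, character(0), "B",
                          c(3, 6, 9, 12))
  expect_equal(hsFree$burial, rep(0, 4), tolerance = 1e-9)

  g <- makeGrooveComplex("GSVAGLSAFDGVAGS",
                         plan = list(list(type = "pocket", peptideRes = 12)))
  hs <- hotspotBurial(g$structure, "A", "B", c(3, 6, 9, 12))
  expect_gt(hs$burial[hs$residue == 12], 0.9)
  expect_lt(max(hs$burial[hs$residue %in% c(3, 6)]), 0.1)
  expect_true(hs$engaged[hs$residue == 12])
})

test_that("glycine hot spots are reported with zero areas and a warning", {
  g <- makeGrooveComplex("GSVAGLSAFDGVAGS")
  expect_warning(hs <- hotspotBurial(g$structure, character(0), "B", 1),
                 "side-chain")
  expect_equal(hs$freeArea, 0)
  expect_false(hs$engaged)
})
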