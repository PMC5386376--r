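test_that("ideal helices have ~3.8 A consecutive Calpha distances", {
  h <- makeHelix(10)
  xyz <- coords(selectCA(h, "A"))
  d <- sqrt(rowSums(diff(xyz)^2))
  # chord length from rise/twist/radius
  chord <- sqrt((2 * 2.3 * sin(50 * pi / 180))^2 + 1.5^2)
  expect_equal(unname(d), rep(chord, 9), tolerance = 1e-9)
  expect_equal(chord, 3.8, tolerance = 0.02)
  # axial span is (n-1) * rise
  expect_equal(max(xyz[, 3]) - min(xyz[, 3]), 9 * 1.5)
  # determinism
  expect_identical(atomRecords(makeHelix(10)), atomRecords(makeHelix(10)))
  expect_error(makeHelix(2), "at least 3")
})

test_that("perturbation is seed-reproducible and sigma-scaled", {
  h <- makeHelix(50)
  expect_identical(atomRecords(perturbStructure(h, 0)),
                   atomRecords(h))
  p1 <- perturbStructure(h, 0.5, seed = 7)
  p2 <- perturbStructure(h, 0.5, seed = 7)
  expect_identical(atomRecords(p1), atomRecords(p2))
  p3 <- perturbStructure(h, 0.5, seed = 8)
  expect_false(identical(atomRecords(p1), atomRecords(p3)))
})

test_that("per-axis noise obeys the sigma*sqrt(3) displacement law", {
  # direct (unsuperposed) RMSD between clean and noised copies; the
  # expected per-atom displacement is sigma * sqrt(3) per axis triplet
  h <- makeHelix(80)
  xyz <- coords(h)
  sigma <- 0.5
  rmsds <- vapply(1:150, function(s) {
    noisy <- coords(perturbStructure(h, sigma, seed = s))
    sqrt(mean(rowSums((noisy - xyz)^2)))
  }, numeric(1))
  se <- sd(rmsds) / sqrt(length(rmsds))
  expect_lt(abs(mean(rmsds) - sigma * sqrt(3)), 4 * se + 1e-3)
})

test_that("generated fixtures roundtrip through structure IO", {
  g <- makeGrooveComplex("GSVAGLSAFDGVAGS",
                         plan = list(list(type = "hbond", peptideRes = 7)))
  f <- tempfile(fileext = ".pdb")
  writeStructure(g$structure, f)
  back <- readStructure(f)
  a1 <- atomRecords(g$structure); a2 <- atomRecords(back)
  expect_equal(nrow(a1), nrow(a2))
  expect_equal(a2$x, a1$x, tolerance = 5e-4)
  expect_identical(a2$name, a1$name)
  expect_identical(a2$chain, a1$chain)
})

test_that("groove complexes realise their contact plans by construction", {
  g <- makeGrooveComplex("GSVAGLSAFDGVAGS", plan = list(
    list(type = "hbond", peptideRes = 7, dist = 2.9),
    list(type = "salt", peptideRes = 10, dist = 3.2)))
  expect_equal(nrow(g$truth$hbonds), 1L)
  expect_equal(g$truth$hbonds$dist, 2.9)
  a <- atomRecords(g$structure)
  og <- a[a$name == "OG" & a$chain == "B" & a$resseq == 7, ]
  oe1 <- a[a$name == "OE1" & a$chain == "A", ]
  d <- sqrt((og$x - oe1$x)^2 + (og$y - oe1$y)^2 + (og$z - oe1$z)^2)
  expect_equal(d, 2.9, tolerance = 1e-9)
  # an infeasible plan (overlapping placement) errors
  expect_error(
    makeGrooveComplex("GSVAGLSAFDGVAGS",
                      plan = list(list(type = "hbond", peptideRes = 7,
                                       dist = 0.5))),
    "infeasible|clash")
})

test_that("motif-bearing sequences embed hits exactly where planned", {
  s <- makeBH3Sequence(71)
  expect_equal(scanBH3(s)$h1, 71L)
  s2 <- makeBH3Sequence(c(15, 45), seed = 3)
  expect_equal(sort(scanBH3(s2)$h1), c(15L, 45L))
  # flank-only sequence: no hit
  flank <- makeBH3Sequence(1, length = 50)
  flankOnly <- gsub("[VLFD]", "G", flank)
  expect_equal(nrow(scanBH3(flankOnly)), 0L)
  # reproducible
  expect_identical(makeBH3Sequence(20, seed = 5),
                   makeBH3Sequence(20, seed = 5))
})

test_that("bundles place the requested number of helices", {
  b <- makeBundle(4, 15)
  expect_equal(nrow(atomRecords(b)), 60L)
  xyz <- coords(b)
  # compact: all helices within the bundle radius + helix radius
  expect_lt(max(abs(xyz[, 1:2])), 6 + 2.3 + 1e-9)
})
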