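test_that("altloc collapse keeps the highest occupancy, ties alphabetical", {
  p <- writeFixturePDB(c(
    pdbAtomLine(1, "N", "SER", "A", 1, 0, 0, 0),
    pdbAtomLine(2, "CA", "SER", "A", 1, 1.0, 0, 0, occ = 0.6,
                altloc = "A"),
    pdbAtomLine(3, "CA", "SER", "A", 1, 1.2, 0, 0, occ = 0.4,
                altloc = "B"),
    pdbAtomLine(4, "OG", "SER", "A", 1, 2.0, 0, 0, occ = 0.5,
                altloc = "B"),
    pdbAtomLine(5, "OG", "SER", "A", 1, 2.2, 0, 0, occ = 0.5,
                altloc = "A"),
    "END"))
  s <- readStructure(p)
  a <- atomRecords(s)
  expect_equal(nrow(a), 3L)                     # one CA, one OG, one N
  expect_equal(a$x[a$name == "CA"], 1.0)        # occupancy 0.6 altloc A
  expect_equal(a$x[a$name == "OG"], 2.2)        # tie -> altloc A

  # order independence: shuffled records give the same collapsed set
  p2 <- writeFixturePDB(c(
    pdbAtomLine(3, "CA", "SER", "A", 1, 1.2, 0, 0, occ = 0.4,
                altloc = "B"),
    pdbAtomLine(5, "OG", "SER", "A", 1, 2.2, 0, 0, occ = 0.5,
                altloc = "A"),
    pdbAtomLine(1, "N", "SER", "A", 1, 0, 0, 0),
    pdbAtomLine(4, "OG", "SER", "A", 1, 2.0, 0, 0, occ = 0.5,
                altloc = "B"),
    pdbAtomLine(2, "CA", "SER", "A", 1, 1.0, 0, 0, occ = 0.6,
                altloc = "A"),
    "END"))
  a2 <- atomRecords(readStructure(p2))
  expect_equal(a2[, c("name", "x")], a[, c("name", "x")])
})

test_that("write/read roundtrip preserves retained fields to 3 decimals", {
  h <- makeHelix(12, sequence = "ASDVLFGKREWT", sidechains = TRUE)
  f <- tempfile(fileext = ".pdb")
  writeStructure(h, f)
  h2 <- readStructure(f)
  a1 <- atomRecords(h); a2 <- atomRecords(h2)
  expect_equal(nrow(a1), nrow(a2))
  for (col in c("name", "resname", "chain", "resseq", "element", "kind"))
    expect_identical(a1[[col]], a2[[col]])
  expect_equal(a2$x, a1$x, tolerance = 5e-4)
  expect_equal(a2$y, a1$y, tolerance = 5e-4)
  expect_equal(a2$z, a1$z, tolerance = 5e-4)
  expect_equal(a2$occupancy, a1$occupancy)
  expect_equal(a2$bfactor, a1$bfactor)
  # a second roundtrip is exact: 3-dp values survive unchanged
  f3 <- tempfile(fileext = ".pdb")
  writeStructure(h2, f3)
  expect_identical(atomRecords(readStructure(f3)), a2)
})

test_that("independent reader agrees on a roundtripped fixture", {
  h <- makeHelix(8, sequence = "ASDVLFGK", sidechains = TRUE)
  f <- tempfile(fileext = ".pdb")
  writeStructure(h, f)
  ref <- bio3d::read.pdb(f)
  mine <- atomRecords(readStructure(f))
  expect_equal(nrow(ref$atom), nrow(mine))
  expect_equal(ref$atom$x, mine$x)
  expect_equal(unname(ref$atom$resid), mine$resname)
})

test_that("malformed records raise errors naming the line", {
  p <- writeFixturePDB(c(
    pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
    "ATOM      2  CA  ALA A   2      bad_coord",
    "END"))
  expect_error(readStructure(p), "line 2")
  empty <- writeFixturePDB(c("HEADER    nothing", "END"))
  expect_error(readStructure(empty), "no ATOM/HETATM")
})

test_that("model selection returns only the requested model", {
  p <- writeFixturePDB(c(
    "MODEL        1",
    pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdbAtomLine(2, "CA", "ALA", "A", 2, 3.8, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdbAtomLine(1, "CA", "ALA", "A", 1, 10, 0, 0),
    pdbAtomLine(2, "CA", "ALA", "A", 2, 13.8, 0, 0),
    "ENDMDL",
    "END"))
  expect_equal(atomRecords(readStructure(p, model = 1))$x[1], 0)
  expect_equal(atomRecords(readStructure(p, model = 2))$x[1], 10)
  expect_error(readStructure(p, model = 3), "empty structure")
})

test_that("atom kinds partition into protein / water / hetero", {
  p <- writeFixturePDB(c(
    pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdbAtomLine(2, "O", "HOH", "W", 101, 5, 5, 5, record = "HETATM"),
    pdbAtomLine(3, "ZN", "ZN", "Z", 201, 8, 8, 8, record = "HETATM",
                element = "ZN"),
    "END"))
  a <- atomRecords(readStructure(p))
  expect_equal(sort(a$kind), c("hetero", "protein", "water"))
  expect_equal(sum(a$kind == "protein") + sum(a$kind == "water") +
                 sum(a$kind == "hetero"), nrow(a))
})

test_that("element inference falls back to the atom-name convention", {
  p <- writeFixturePDB(c(
    pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdbAtomLine(2, "OG", "SER", "A", 2, 1, 0, 0),
    pdbAtomLine(3, "NZ", "LYS", "A", 3, 2, 0, 0),
    "END"))
  a <- atomRecords(readStructure(p))
  expect_equal(a$element, c("C", "O", "N"))
})

test_that("selectCA returns ordered Calphas and warns on missing ones", {
  h <- makeHelix(5, sequence = "ASDVL", sidechains = TRUE)
  cs <- selectCA(h, "A")
  expect_equal(length(residueLabels(cs)), 5L)
  expect_equal(residueNames(cs), c("ALA", "SER", "ASP", "VAL", "LEU"))
  # drop one CA: 4 rows plus a warning
  a <- atomRecords(h)
  s2 <- newStructure(a[!(a$resseq == 3 & a$name == "CA"), ])
  expect_warning(cs2 <- selectCA(s2, "A"), "lack a Calpha")
  expect_equal(nrow(coords(cs2)), 4L)
  expect_error(selectCA(h, "Q"), "available")
})

test_that("writeStructure rejects empty and overflowing structures", {
  h <- makeHelix(4)
  expect_error(
    writeStructure(initialize(h, atoms = atomRecords(h)[0, ]),
                   tempfile()), "empty")
  a <- atomRecords(h)
  a$x[1] <- 123456.0
  expect_error(writeStructure(newStructure(a), tempfile()), "overflow")
})
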