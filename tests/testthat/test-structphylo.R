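makeToyMSA <- function(n = 3, sigma = c(0, 0.5, 1.0), seed = 100,
                       gaps = NULL) {
  base <- makeBundle(4, 15)
  structures <- list()
  seqs <- character(0)
  chains <- character(0)
  plain <- paste(rep("A", 60), collapse = "")
  for (i in seq_len(n)) {
    id <- paste0("s", i)
    structures[[id]] <- if (sigma[i] == 0) base else
      perturbStructure(base, sigma[i], seed = seed + i)
    seqs[id] <- plain
    chains[id] <- "A"
  }
  structureAlignment(seqs, structures, chains)
}

test_that("equivalent pairs follow the alignment columns and gaps", {
  msa <- makeToyMSA()
  pr <- equivalentCAPairs(msa, "s1", "s2")
  expect_equal(nrow(pr$a), 60L)                    # gapless: all columns
  expect_equal(pr$labelsA, pr$labelsB)

  # gap 3 columns in one row: those columns are dropped
  h1 <- makeHelix(10); h2 <- makeHelix(7)
  seqs <- c(x = "AAAAAAAAAA", y = "AAA---AAAA")
  msa2 <- structureAlignment(seqs, list(x = h1, y = h2),
                             c(x = "A", y = "A"))
  pr2 <- equivalentCAPairs(msa2, "x", "y")
  expect_equal(nrow(pr2$a), 10L - 3L)
  expect_equal(pr2$columns, c(1:3, 7:10))

  # alignment row not matching the modelled chain length is an error
  bad <- structureAlignment(c(x = "AAAA", y = "AAAA"),
                            list(x = h1, y = h2), c(x = "A", y = "A"))
  expect_error(equivalentCAPairs(bad, "x", "y"), "modelled")
})

test_that("rmsd matrix is symmetric, zero-diagonal, ordered with noise", {
  msa <- makeToyMSA(4, sigma = c(0, 0.5, 1.0, 2.0))
  m <- rmsdMatrix(msa)
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_equal(unname(diag(m)), rep(0, 4))
  expect_true(all(m[upper.tri(m)] >= 0))
  # distances from the clean copy grow monotonically with sigma
  expect_true(m["s1", "s2"] < m["s1", "s3"])
  expect_true(m["s1", "s3"] < m["s1", "s4"])
  # rigid copies of one structure give an all-zero matrix
  base <- makeBundle(3, 12)
  copies <- list(a = base,
                 b = rigidMove(base, randomRotation(1), c(1, 2, 3)),
                 c = rigidMove(base, randomRotation(2), c(-5, 0, 2)))
  plain <- paste(rep("A", 36), collapse = "")
  msa0 <- structureAlignment(setNames(rep(plain, 3), names(copies)),
                             copies, setNames(rep("A", 3), names(copies)))
  expect_equal(max(rmsdMatrix(msa0)), 0, tolerance = 1e-9)
})

test_that("average linkage reproduces an ultrametric toy matrix", {
  m <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- clusterStructures(m, linkage = "average")
  expect_equal(tr$height, c(2, 6))
  # first merge is {A, B}
  expect_equal(sort(tr$labels[-tr$merge[1, ]]), c("A", "B"))
  nwk <- toNewick(tr)
  ph <- ape::read.tree(text = nwk)
  # leaf depths follow the height/2 convention: A,B at 1+2=3, C at 3
  depth <- ape::node.depth.edgelength(ph)[1:3]
  expect_equal(unname(depth[match(c("A", "B", "C"), ph$tip.label)]),
               c(3, 3, 3))
  ab <- ape::getMRCA(ph, c("A", "B"))
  expect_equal(ape::node.depth.edgelength(ph)[ab], 2)  # depth 3 - 1
})

test_that("clustering is invariant under label permutation", {
  set.seed(42)
  n <- 6
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 1, 10)
  d <- d + t(d)
  ids <- paste0("t", 1:n)
  dimnames(d) <- list(ids, ids)
  perm <- sample(n)
  t1 <- clusterStructures(d)
  t2 <- clusterStructures(d[perm, perm])
  p1 <- ape::as.phylo(t1); p2 <- ape::as.phylo(t2)
  expect_equal(sort(t1$height), sort(t2$height))
  expect_true(ape::all.equal.phylo(p1, p2, use.edge.length = TRUE))
})

test_that("an outlier structure joins the tree last", {
  # two tight groups and a lone outlier, as in structure-family trees
  ids <- c("g1a", "g1b", "g2a", "g2b", "lone")
  m <- matrix(8, 5, 5, dimnames = list(ids, ids))
  m[1, 2] <- m[2, 1] <- 1
  m[3, 4] <- m[4, 3] <- 1.5
  m[5, ] <- m[, 5] <- 20
  diag(m) <- 0
  tr <- clusterStructures(m)
  # the last merge brings in the singleton "lone"
  last <- tr$merge[nrow(tr$merge), ]
  expect_true(any(last == -which(ids == "lone")))
  expect_equal(max(tr$height), 20)
})

test_that("cluster input validation catches bad matrices", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(clusterStructures(m), "symmetric")
  m2 <- matrix(c(0.5, 1, 1, 0), 2, 2)
  expect_error(clusterStructures(m2), "diagonal")
  m3 <- matrix(c(0, NA, NA, 0), 2, 2)
  expect_error(clusterStructures(m3), "missing")
})

test_that("newick export handles the degenerate single-leaf case", {
  expect_equal(toNewick("A"), "A;")
})
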