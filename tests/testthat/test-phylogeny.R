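# Supermatrix assembly, column filtering, distances, neighbor joining
# (with a least-squares quartet oracle), bootstrap and tree comparison.

aln_from <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(rows)
  m
}

test_that("supermatrix concatenation sums lengths and keeps provenance", {
  a1 <- aln_from(t1 = "MKLVA", t2 = "MKLVA", t3 = "MRLVA")
  a2 <- aln_from(t1 = "HHQWERT", t2 = "HHQWERT", t3 = "HHQWERA")
  sm <- concatenateSingleCopy(list(f1 = a1, f2 = a2), c("t1", "t2", "t3"))
  expect_equal(ncol(sm), 12L)
  expect_equal(unname(attr(sm, "partition")), c(5L, 7L))
  one <- concatenateSingleCopy(list(f1 = a1), c("t1", "t2", "t3"))
  expect_equal(one[, 1:5], a1[c("t1", "t2", "t3"), ])
  expect_error(concatenateSingleCopy(list(), c("t1")), "no alignments")
  expect_error(concatenateSingleCopy(list(f1 = a1), c("t1", "t4")), "t4")
})

test_that("column filtering removes gappy and unconserved positions", {
  clean <- aln_from(t1 = "AAAA", t2 = "AAAA", t3 = "AAAA", t4 = "AAAA")
  expect_equal(attr(filterColumns(clean), "removed"), 0L)

  gappy <- aln_from(t1 = "A-", t2 = "A-", t3 = "A-", t4 = "AC")
  out <- filterColumns(gappy, max_gap_fraction = 0.5)
  expect_equal(ncol(out), 1L)          # 3/4 gaps removed
  div <- aln_from(t1 = "AA", t2 = "AC", t3 = "AG", t4 = "AT")
  out2 <- filterColumns(div, min_conservation = 0.5)
  expect_equal(ncol(out2), 1L)         # second column max freq 1/4
  expect_error(filterColumns(aln_from(t1 = "-", t2 = "-")), "all columns")
})

test_that("p and Poisson distances behave as defined", {
  id <- aln_from(a = "MKLV", b = "MKLV")
  expect_equal(alignmentDistance(id, "p_distance")["a", "b"], 0)
  half <- aln_from(a = "AAAA", b = "AACC")
  expect_equal(alignmentDistance(half, "p_distance")["a", "b"], 0.5)
  expect_equal(alignmentDistance(half, "poisson")["a", "b"], -log(0.5))
  sat <- aln_from(a = "AAAA", b = "CCCC")
  expect_error(alignmentDistance(sat, "poisson"), "saturated")
  set.seed(1)
  r <- aln_from(a = "ARNDC", b = "RNDCA", c = "NDCAR")
  d <- alignmentDistance(r, "p_distance")
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(19)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.2, 1.5)
    dm <- ape::cophenetic.phylo(tr)
    nj <- njTree(dm)
    expect_equal(rfDistance(nj, tr), 0L)
    # path metric of the reconstruction reproduces the input distances
    dm2 <- ape::cophenetic.phylo(nj)[rownames(dm), colnames(dm)]
    expect_equal(dm2, dm, tolerance = 1e-8)
    if (n == 4) {
      # independent least-squares enumeration of the three topologies
      sis <- ls_quartet(dm)
      nj_split <- ape::prop.part(ape::unroot(nj))
      parts <- lapply(nj_split, function(ix) sort(nj$tip.label[ix]))
      nontriv <- parts[lengths(parts) == 2]
      flip <- lapply(nontriv, function(p) sort(setdiff(nj$tip.label, p)))
      expect_true(any(vapply(c(nontriv, flip),
                             function(p) identical(p, sis), TRUE)))
    }
  }
})

test_that("3-taxon NJ uses the three-point formulas", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(dm)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["c"]), (4 + 5 - 3) / 2)
  expect_error(njTree(dm[1:2, 1:2]), "3 taxa")
})

test_that("NJ topology is invariant to taxon input order", {
  set.seed(4)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.2, 1)
  dm <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(dm))
  t1 <- njTree(dm)
  t2 <- njTree(dm[perm, perm])
  expect_equal(rfDistance(t1, t2), 0L)
})

test_that("bootstrap supports are percentages, seeded, and high for clean splits", {
  # two clearly separated 3-taxon clades: many fixed differences across the
  # split, none within
  left <- paste(rep("A", 120), collapse = "")
  right <- paste(rep("R", 120), collapse = "")
  aln <- aln_from(l1 = left, l2 = left, l3 = left,
                  r1 = right, r2 = right, r3 = right)
  # add mild within-clade noise so distances are finite and distinct
  set.seed(9)
  for (r in 1:6) {
    pos <- sample(120, 8)
    aln[r, pos] <- sample(c("N", "D", "C", "Q"), 8, replace = TRUE)
  }
  bt <- bootstrapSupport(aln, model = "p_distance", n_reps = 100, seed = 2)
  expect_true(all(bt$node.label >= 0 & bt$node.label <= 100))
  # the left/right bipartition is an internal edge with near-total support
  expect_true(max(bt$node.label[-1]) >= 95)
  bt2 <- bootstrapSupport(aln, model = "p_distance", n_reps = 100, seed = 2)
  expect_identical(bt$node.label, bt2$node.label)
})

test_that("gene-content tree distances are Manhattan/Hamming counts", {
  m <- cbind(A = c(0, 1, 1, 0), B = c(1, 1, 0, 0), C = c(1, 1, 1, 1),
             D = c(0, 0, 0, 1))
  rownames(m) <- paste0("f", 1:4)
  d <- as.matrix(dist(t(m), method = "manhattan"))
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "B"], sum(m[, "A"] != m[, "B"]))   # Hamming identity
  tr <- manhattanTree(m)
  expect_setequal(tr$tip.label, colnames(m))
  # identical genome columns collapse to distance zero
  m2 <- cbind(m, E = m[, "A"])
  tr2 <- manhattanTree(m2)
  bl <- setNames(tr2$edge.length, tr2$tip.label[tr2$edge[, 2]])
  expect_equal(unname(bl["A"]) + unname(bl["E"]), 0)
})

test_that("Robinson-Foulds distance obeys its identities", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rfDistance(t1, t1), 0L)
  expect_equal(rfDistance(t1, t2), 2L)
  perm <- ape::read.tree(text = "((d,c),(b,a));")
  expect_equal(rfDistance(t1, perm), 0L)
  t3 <- ape::read.tree(text = "((a,b),(c,e));")
  expect_error(rfDistance(t1, t3), "leaf set")
})

test_that("supermatrix tree matches the species tree on clean data", {
  ok <- 0
  for (s in 1:10) {
    dat <- sim_family_dataset(0.2, n_taxa = 7, n_families = 12, codons = 80,
                              scale = 0.3, seed = 100 + s)
    mem <- familyMembership(dat$truth)
    alns <- lapply(split(mem, mem$family), function(fm) {
      m <- alignmentMatrix(proteinSeqs(dat$genes)[fm$gene])
      rownames(m) <- fm$genome
      m
    })
    sm <- concatenateSingleCopy(alns, dat$tree$tip.label)
    tr <- njTree(alignmentDistance(filterColumns(sm), "poisson"))
    if (rfDistance(tr, dat$tree) == 0) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
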