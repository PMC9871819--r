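# Distances, neighbor joining, bootstrap, rooting, collapsing, iTOL.

test_that("protein distances follow the Kimura correction with saturation ceiling", {
  msa <- ProteinMSA(c(a = "MKVLAWMKVL", b = "MKVLAWMKVL"))
  expect_equal(unname(proteinDistance(msa)["a", "b"]), 0)

  # p = 0.5 -> -ln(0.45)
  msa2 <- ProteinMSA(c(a = "AAAACCCC", b = "AAAAGGGG"))
  expect_equal(unname(proteinDistance(msa2)["a", "b"]),
               -log(1 - 0.5 - 0.2 * 0.25), tolerance = 1e-12)

  # saturated pair hits the ceiling
  msa3 <- ProteinMSA(c(a = "AAAAAAAAAA", b = "CCCCCCCCCC"))
  expect_equal(unname(proteinDistance(msa3)["a", "b"]), 5.0)

  # oracle: independent per-pair recount on a gapped toy msa
  set.seed(71)
  msa4 <- randMsa(6, 30, gapFrac = 0.2)
  D <- proteinDistance(msa4)
  m <- msaMatrix(msa4)
  for (i in 1:5) for (j in (i + 1):6) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    p <- mean(m[i, ok] != m[j, ok])
    d <- if (p >= 0.85) 5.0 else -log(1 - p - 0.2 * p^2)
    expect_equal(D[i, j], d, tolerance = 1e-12)
  }
  expect_true(isSymmetric(D))
  expect_error(proteinDistance(
    ProteinMSA(c(a = "A-", b = "-C"))), "incomparable-pair")
})

test_that("neighbor joining is exact on additive matrices (randomized battery)", {
  set.seed(75)
  for (case in 1:50) {
    n <- sample(5:8, 1)
    phy <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    D <- treeDistances(phy)
    st <- neighborJoining(D)
    expect_equal(phangorn::RF.dist(ape::unroot(phy), asPhylo(st)), 0)
    # branch lengths: distances round-trip
    D2 <- treeDistances(asPhylo(st))[rownames(D), colnames(D)]
    expect_equal(D2, D, tolerance = 1e-6)
  }
  # 3 taxa: closed-form three-point solution
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  st3 <- neighborJoining(D3)
  phy3 <- asPhylo(st3)
  len <- setNames(phy3$edge.length, phy3$tip.label[phy3$edge[, 2]])
  expect_equal(unname(len[c("a", "b", "c")]), c(1, 2, 3))
  expect_error(neighborJoining(D3[1:2, 1:2]), "invalid-argument")

  # star-like equidistant taxa: total length equals the closed form
  Ds <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(Ds) <- 0
  expect_equal(sum(asPhylo(neighborJoining(Ds))$edge.length), 4)
})

test_that("NJ agrees with an established implementation on noisy matrices", {
  set.seed(76)
  for (case in 1:10) {
    phy <- ape::rtree(7, br = function(k) runif(k, 0.2, 1))
    D <- treeDistances(phy)
    noise <- matrix(runif(49, -0.02, 0.02), 7)
    D <- D + (noise + t(noise)) / 2
    diag(D) <- 0
    ours <- asPhylo(neighborJoining(D))
    ref <- ape::nj(as.dist(D))
    expect_equal(phangorn::RF.dist(ours, ref), 0)
  }
})

test_that("bootstrap supports are reproducible, bounded and leaf-order invariant", {
  set.seed(81)
  # two well-separated clades with low within-clade divergence
  mkclade <- function(prefix, base) {
    vapply(1:4, function(i) {
      ch <- strsplit(base, "")[[1]]
      k <- sample(length(ch), 3)
      ch[k] <- sample(AA, 3, TRUE)
      paste(ch, collapse = "")
    }, character(1))
  }
  b1 <- randSeq(60); b2 <- randSeq(60)
  rows <- setNames(c(mkclade("x", b1), mkclade("y", b2)),
                   c(paste0("x", 1:4), paste0("y", 1:4)))
  msa <- ProteinMSA(rows)
  st <- bootstrapSupports(msa, nReps = 100, seed = 7)
  sup <- nodeSupport(st)
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  # the deep split is near-certain
  keys <- ftszprov:::bipartitionKeys(asPhylo(st))
  deep <- paste(sort(paste0("y", 1:4)), collapse = "\r")
  i <- match(deep, keys)
  expect_false(is.na(i))
  ntip <- 8
  expect_gte(sup[as.integer(names(keys)[i]) - ntip], 95)

  st2 <- bootstrapSupports(msa, nReps = 100, seed = 7)
  expect_identical(nodeSupport(st2), sup)

  perm <- ProteinMSA(rows[sample(8)])
  st3 <- bootstrapSupports(perm, nReps = 100, seed = 7)
  k3 <- ftszprov:::bipartitionKeys(asPhylo(st3))
  s3 <- nodeSupport(st3)[as.integer(names(k3)) - ntip]
  s1 <- nodeSupport(st)[as.integer(names(keys)) - ntip]
  expect_equal(sort(setNames(s3, k3)[names(sort(setNames(s1, keys)))]),
               sort(setNames(s1, keys)), tolerance = 1e-9)
})

test_that("midpoint rooting matches arithmetic, symmetry and a brute-force scan", {
  # 2-leaf tree, branches 3 and 1 -> root 2.0 from each leaf
  t2 <- SupportTree(ape::read.tree(text = "(a:3,b:1);"), rooted = FALSE)
  r2 <- midpointRoot(t2)
  phy2 <- asPhylo(r2)
  expect_true(ape::is.rooted(phy2))
  expect_equal(sort(phy2$edge.length), c(2, 2))

  # balanced ultrametric tree roots at its original root
  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  rb <- midpointRoot(SupportTree(ape::unroot(bal)))
  expect_equal(phangorn::RF.dist(asPhylo(rb), bal), 0)
  depths <- ape::node.depth.edgelength(asPhylo(rb))
  expect_equal(unname(depths[1:4]), rep(2, 4))

  # 20 random trees vs brute-force edge scan of the minimax point
  set.seed(85)
  for (case in 1:20) {
    phy <- ape::unroot(ape::rtree(sample(5:9, 1),
                                  br = function(k) runif(k, 0.05, 1)))
    r <- asPhylo(midpointRoot(SupportTree(phy)))
    got <- max(ape::node.depth.edgelength(r)[seq_along(r$tip.label)])
    want <- bruteMidpoint(phy)$val
    expect_equal(got, want, tolerance = 2e-2)
  }
  zero <- ape::read.tree(text = "(a:0,b:0,c:0);")
  expect_error(midpointRoot(SupportTree(zero)), "degenerate-tree")
})

test_that("rooting preserves the bipartition set and supports travel with edges", {
  set.seed(86)
  msa <- randMsa(7, 50, gapFrac = 0.05)
  st <- bootstrapSupports(msa, nReps = 50, seed = 3)
  rooted <- midpointRoot(st)
  k1 <- ftszprov:::bipartitionKeys(asPhylo(st))
  k2 <- ftszprov:::bipartitionKeys(ape::unroot(asPhylo(rooted)))
  expect_setequal(unname(k1), unname(k2))
  ntip <- 7
  s1 <- setNames(nodeSupport(st)[as.integer(names(k1)) - ntip], k1)
  s2 <- setNames(nodeSupport(rooted)[as.integer(names(ftszprov:::bipartitionKeys(
    asPhylo(rooted)))) - ntip], ftszprov:::bipartitionKeys(asPhylo(rooted)))
  shared <- intersect(names(s1), names(s2))
  expect_equal(s2[shared], s1[shared])
})

test_that("low-support collapse contracts exactly the weak bipartitions", {
  set.seed(87)
  msa <- randMsa(8, 40, gapFrac = 0.1)
  st <- bootstrapSupports(msa, nReps = 50, seed = 9)
  expect_identical(asPhylo(collapseLowSupport(st, 0))$edge,
                   asPhylo(st)$edge)

  allCol <- collapseLowSupport(st, 101)          # everything goes
  expect_equal(asPhylo(allCol)$Nnode, 1L)        # star tree

  thr <- 60
  col <- collapseLowSupport(st, thr)
  keysB <- ftszprov:::bipartitionKeys(asPhylo(st))
  supB <- nodeSupport(st)[as.integer(names(keysB)) - 8]
  surviving <- unname(keysB[supB >= thr])
  expect_setequal(unname(ftszprov:::bipartitionKeys(asPhylo(col))),
                  surviving)
  # child edge lengths unchanged for surviving leaves
  l1 <- setNames(asPhylo(st)$edge.length,
                 asPhylo(st)$edge[, 2])[as.character(1:8)]
  l2 <- setNames(asPhylo(col)$edge.length,
                 asPhylo(col)$edge[, 2])[as.character(1:8)]
  expect_equal(unname(l2), unname(l1), tolerance = 1e-9)
})

test_that("newick support round-trip and iTOL color strip round-trip", {
  set.seed(88)
  msa <- randMsa(6, 40, gapFrac = 0.1)
  st <- bootstrapSupports(msa, nReps = 20, seed = 2)
  f <- tempfile(fileext = ".nwk")
  writeSupportNewick(st, f)
  st2 <- readSupportNewick(f)
  expect_equal(phangorn::RF.dist(asPhylo(st), asPhylo(st2)), 0)
  k <- ftszprov:::bipartitionKeys(asPhylo(st))
  k2 <- ftszprov:::bipartitionKeys(asPhylo(st2))
  s1 <- setNames(nodeSupport(st)[as.integer(names(k)) - 6], k)
  s2 <- setNames(nodeSupport(st2)[as.integer(names(k2)) - 6], k2)
  expect_equal(s2[names(s1)], s1, tolerance = 1e-6)

  classes <- setNames(rep(c("P1", "P2"), 3), names(msaRows(msa)))
  ff <- tempfile(fileext = ".txt")
  writeItolColorStrip(st, classes, ff)
  lines <- readLines(ff)
  expect_equal(sum(seq_along(lines) > which(lines == "DATA")), 6)
  expect_equal(readItolColorStrip(ff)[names(classes)], classes)
  expect_error(writeItolColorStrip(st, classes[-1], ff), "missing-id")
})
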