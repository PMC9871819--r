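# Species-tree / family-evolution / genome-emission simulator.

test_that("species trees are ultrametric with complete four-rank taxonomy", {
  sp2 <- simulateSpeciesTree(2, seed = 7)
  d <- ape::node.depth.edgelength(sp2$tree)
  expect_equal(unname(d[1:2]), c(1, 1))             # equal root-to-tip

  sp <- simulateSpeciesTree(16, seed = 1)
  expect_equal(length(sp$tree$tip.label), 16L)
  expect_equal(sp$tree$Nnode, 15L)                   # binary: 2n - 1 nodes
  expect_true(ape::is.ultrametric(sp$tree, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(sp$tree)), 1, tolerance = 1e-8)
  tx <- sp$taxonomy
  expect_equal(nrow(tx), 16L)
  expect_true(all(nzchar(as.matrix(tx))))
  expect_setequal(unique(tx$domain), c("Bacteria-like", "Archaea-like"))
  expect_error(simulateSpeciesTree(1), "invalid-argument")
})

test_that("taxonomy ranks agree with a brute-force tree-cut recount", {
  # oracle: independently cut each tree at the fixed rank depths and
  # count groups; compare with the emitted labels over replicates
  for (seed in 1:25) {
    sp <- simulateSpeciesTree(24, seed = seed)
    phy <- sp$tree
    depth <- ape::node.depth.edgelength(phy)
    for (rank in c(phylum = 0.25, class = 0.5, order = 0.75)) {
      # group = edge crossing the cut on the root-to-leaf path
      anchors <- vapply(seq_len(24), function(l) {
        path <- ape::nodepath(phy, 25, l)
        path[which(depth[path] > rank)[1]]
      }, numeric(1))
      lab <- sp$taxonomy[[names(which(c(phylum = 0.25, class = 0.5,
                                        order = 0.75) == rank))]]
      expect_equal(length(unique(lab)), length(unique(anchors)))
      expect_true(all(table(lab, anchors) %in%
                        c(0, table(anchors))))       # 1:1 grouping
    }
  }
})

test_that("zero-length branches copy the root sequence; events are bookkept", {
  sp <- simulateSpeciesTree(2, seed = 3)
  sp$tree$edge.length <- rep(0, length(sp$tree$edge.length))
  fam <- evolveFamily(sp, seed = 5)
  seqs <- as.character(sequences(fam$records))
  expect_equal(length(seqs), 2L)
  expect_identical(seqs[[1]], seqs[[2]])             # zero divergence

  # duplication at the root stem of one domain -> 2 genes per genome there
  sp8 <- simulateSpeciesTree(8, seed = 11)
  stem <- stemBranchOf(sp8, "Archaea-like")
  stemLen <- sp8$tree$edge.length[sp8$tree$edge[, 2] == stem]
  fam2 <- evolveFamily(sp8, schedule = simEvent("duplication", stem,
                                                stemLen / 2,
                                                newLabel = "ftsZ2"),
                       seed = 12)
  counts <- fam2$truth$geneCounts
  tx <- sp8$taxonomy
  arch <- tx$genome[tx$domain == "Archaea-like"]
  expect_true(all(counts$n_genes[counts$genome %in% arch] == 2))
  expect_true(all(counts$n_genes[!counts$genome %in% arch] == 1))
  lab <- fam2$truth$sequences
  expect_setequal(unique(lab$label[lab$genome %in% arch]),
                  c("ftsZ", "ftsZ2"))
  # every record appears exactly once in the truth table
  expect_setequal(lab$seq_id, names(fam2$records))
  expect_equal(anyDuplicated(lab$seq_id), 0L)

  # inconsistent schedules are rejected with the offending event id
  expect_error(evolveFamily(sp8, schedule = simEvent("duplication", stem,
                                                     stemLen * 2)),
               "schedule-error \\(e01\\)")
  expect_error(evolveFamily(sp8, schedule = simEvent("lgt", stem, stemLen / 2,
                                                     donor = stem)),
               "schedule-error")
})

test_that("segment divergence scales with conservation as an independent CTMC predicts", {
  # oracle: an independent direct CTMC sampler over the same rate
  # matrix, run at the same effective times
  model <- ftszprov:::dayhoffModel()
  simIdent <- function(teff, n, reps) {
    P <- ftszprov:::pmatrix(teff, model)
    mean(vapply(seq_len(reps), function(i) {
      a <- sample.int(20, n, TRUE, prob = model$bf)
      b <- vapply(a, function(x) sample.int(20, 1, prob = P[x, ]), 1L)
      mean(a == b)
    }, numeric(1)))
  }
  set.seed(21)
  sp <- simulateSpeciesTree(2, seed = 31)            # two leaves, depth 1
  arch <- familyArchitecture(ntermLength = 150, ctermLength = 150,
                             ntermConservation = 0.95,
                             ctermConservation = 0.40)
  obs <- matrix(0, 2, 0)
  for (seed in 1:40) {
    fam <- evolveFamily(sp, arch = arch, seed = seed)
    tr <- fam$truth
    # compare only mutually surviving ancestral columns per segment
    k1 <- tr$keys[[1]]; k2 <- tr$keys[[2]]
    shared1 <- intersect(k1[[1]], k2[[1]])
    shared2 <- intersect(k1[[2]], k2[[2]])
    aaOf <- function(id, seg, keys) {
      s <- strsplit(as.character(sequences(fam$records)[[id]]), "")[[1]]
      segkeys <- tr$keys[[id]][[seg]]
      off <- if (seg == 2) length(tr$keys[[id]][[1]]) else 0
      s[off + match(keys, segkeys)]
    }
    id1 <- names(fam$records)[1]; id2 <- names(fam$records)[2]
    obs <- cbind(obs, c(mean(aaOf(id1, 1, shared1) == aaOf(id2, 1, shared1)),
                        mean(aaOf(id1, 2, shared2) == aaOf(id2, 2, shared2))))
  }
  # both leaves at depth 1 -> pairwise time 2; rates 0.05 and 0.6
  exp1 <- simIdent(2 * 0.05, 150, 200)
  exp2 <- simIdent(2 * 0.60, 150, 200)
  expect_lt(abs(mean(obs[1, ]) - exp1), 0.02)
  expect_lt(abs(mean(obs[2, ]) - exp2), 0.02)
  expect_gt(mean(obs[1, ]), mean(obs[2, ]))          # monotone in conservation
})

test_that("identical seeds give byte-identical corpora; distinct seeds differ", {
  a <- simulateCorpus(nTaxa = 8, scenario = "plain", seed = 42)
  b <- simulateCorpus(nTaxa = 8, scenario = "plain", seed = 42)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  writeSimulatedCorpus(a, d1); writeSimulatedCorpus(b, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  c3 <- simulateCorpus(nTaxa = 8, scenario = "plain", seed = 43)
  writeSimulatedCorpus(c3, d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "family.faa"))),
                         unname(tools::md5sum(file.path(d3, "family.faa")))))
})

test_that("emitted genomes embed focal genes in clade templates with sane coordinates", {
  sim <- simulateCorpus(nTaxa = 8, scenario = "plain", seed = 9)
  gt <- sim$geneTable
  expect_true(all(gt$start >= 1))
  expect_true(all(gt$end > gt$start))
  expect_true(all(gt$strand %in% c("+", "-")))
  # per-genome genes are non-overlapping and sorted blocks
  for (g in unique(gt$genome)) {
    rows <- gt[gt$genome == g, ]
    rows <- rows[order(rows$start), ]
    expect_true(all(diff(rows$start) > 0))
    expect_true(all(utils::head(rows$end, -1) < utils::tail(rows$start, -1)))
  }
  # focal genes present once per family record
  focal <- gt$gene_id[startsWith(gt$truth_domain, "focal")]
  expect_setequal(focal, names(sim$records))
  # unknown clade template -> configuration error
  expect_error(emitGenomes(sim$records, sim$taxonomy,
                           templates = list(NoSuchClade =
                             defaultNeighborhoodTemplates()[[1]])),
               "configuration-error")
})

test_that("lateral transfer adds the donor lineage's gene to the recipient", {
  sp <- simulateSpeciesTree(8, seed = 51)
  phy <- sp$tree
  # recipient: bacterial stem; donor: archaeal stem (both span the
  # same early interval, so they coexist at the event time)
  bStem <- stemBranchOf(sp, "Bacteria-like")
  aStem <- stemBranchOf(sp, "Archaea-like")
  elen <- setNames(phy$edge.length, phy$edge[, 2])
  fam <- evolveFamily(sp, schedule = simEvent("lgt", bStem,
                                              elen[[as.character(bStem)]] / 2,
                                              donor = aStem,
                                              newLabel = "ftsZ_lgt"),
                      seed = 52)
  tr <- fam$truth$sequences
  tx <- sp$taxonomy
  bactG <- tx$genome[tx$domain == "Bacteria-like"]
  expect_setequal(tr$genome[tr$label == "ftsZ_lgt"], bactG)
  # losses remove the targeted paralog downstream
  fam2 <- evolveFamily(sp, schedule = rbind(
    simEvent("lgt", bStem, elen[[as.character(bStem)]] / 2,
             donor = aStem, newLabel = "ftsZ_lgt"),
    simEvent("loss", match(bactG[1], phy$tip.label), 0, target = "ftsZ")),
    seed = 52)
  tr2 <- fam2$truth$sequences
  expect_false("ftsZ" %in% tr2$label[tr2$genome == bactG[1]])
  expect_true("ftsZ_lgt" %in% tr2$label[tr2$genome == bactG[1]])
})
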