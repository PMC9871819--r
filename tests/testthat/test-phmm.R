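# Profile-HMM construction, scoring, calibration and search.

test_that("model building follows the documented emission and match-column rules", {
  # single ungapped all-G column, no pseudocounts -> M = 1, P(G) = 1
  h <- buildProfileHMM(ProteinMSA(c(a = "G", b = "G", c = "G")),
                       pseudocount = 0, name = "g")
  expect_equal(hmmLength(h), 1L)
  expect_equal(unname(h@match[1, "G"]), 1.0)

  # occupancy threshold arithmetic: one 50%-gap column at occupancy 0.6
  msa <- ProteinMSA(c(a = "ACD", b = "ACD", c = "A-D", d = "A-D"))
  expect_equal(hmmLength(buildProfileHMM(msa, occupancy = 0.6)), 2L)
  expect_equal(hmmLength(buildProfileHMM(msa, occupancy = 0.5)), 3L)

  # pseudocount formula: (count + w*bg) / (n + w), every cell
  msa3 <- ProteinMSA(c(a = "AG", b = "AG", c = "CG"))
  h3 <- buildProfileHMM(msa3, pseudocount = 0.1)
  bg <- backgroundFrequencies()
  expected <- function(cnt, aa) (cnt + 0.1 * bg[[aa]]) / (3 + 0.1)
  expect_equal(unname(h3@match[1, "A"]), expected(2, "A"))
  expect_equal(unname(h3@match[1, "C"]), expected(1, "C"))
  expect_equal(unname(h3@match[1, "G"]), expected(0, "G"))
  expect_equal(unname(h3@match[2, "G"]), expected(3, "G"))
  expect_equal(sum(h3@match[1, ]), 1, tolerance = 1e-12)

  # degenerate: all-gap columns only
  expect_error(buildProfileHMM(ProteinMSA(c(a = "--", b = "--", c = "AC")),
                               occupancy = 0.9),
               "model-degenerate")
})

test_that("forward bits match the glocal single-path value and reject bad input", {
  h <- buildProfileHMM(ProteinMSA(c(a = "A", b = "A", c = "A")),
                       pseudocount = 0, name = "one")
  expect_equal(forwardBits(h, "A", "glocal"),
               log2(1 / backgroundFrequencies()[["A"]]),
               tolerance = 1e-10)
  expect_error(forwardBits(h, "AZJ"), "alphabet-error")
  expect_error(forwardBits(h, ""), "invalid-argument")
})

test_that("forward equals the exhaustive path-enumeration oracle (randomized battery)", {
  set.seed(101)
  worst <- 0
  for (case in 1:100) {
    M <- sample(1:3, 1); L <- sample(1:6, 1)
    msa <- ProteinMSA(setNames(
      replicate(4, paste(sample(AA, M, replace = TRUE), collapse = "")),
      paste0("s", 1:4)))
    h <- buildProfileHMM(msa, name = "case")
    s <- randSeq(L)
    mode <- if (case %% 2) "local" else "glocal"
    f <- forwardBits(h, s, mode)
    o <- enumForwardBits(h, s, mode)
    if (is.finite(f) || is.finite(o))
      worst <- max(worst, abs(f - o))
  }
  expect_lt(worst, 1e-9)
})

test_that("forward dominates viterbi and null scores have negative median", {
  set.seed(7)
  msa <- familyMsa(6, 40)
  h <- buildProfileHMM(msa, name = "fam")
  for (i in 1:20) {
    s <- randSeq(sample(20:60, 1))
    expect_gte(forwardBits(h, s), viterbiHit(h, s)$bits - 1e-9)
  }
  nulls <- vapply(1:500, function(i)
    forwardBits(h, randSeq(40, backgroundFrequencies())), numeric(1))
  expect_lt(median(nulls), 0)
})

test_that("viterbi envelope recovers an implanted consensus and breaks ties leftmost", {
  set.seed(11)
  msa <- familyMsa(6, 25, noise = 0.05)
  h <- buildProfileHMM(msa, name = "imp")
  cons <- hmmConsensus(h)
  # consensus scored alone: envelope covers it exactly
  hit <- viterbiHit(h, cons)
  expect_equal(hit$env_start, 0L)
  expect_equal(hit$env_end, nchar(cons))

  # implanted at positions 11..35 (1-based) of a 100-mer
  hits <- replicate(50, {
    flank1 <- randSeq(10, backgroundFrequencies())
    flank2 <- randSeq(65, backgroundFrequencies())
    v <- viterbiHit(h, paste0(flank1, cons, flank2))
    c(v$env_start, v$env_end)
  })
  expect_true(all(hits[1, ] >= 8 & hits[1, ] <= 12))
  expect_true(all(hits[2, ] >= 33 & hits[2, ] <= 37))

  # two identical placements: the leftmost is returned
  m1 <- buildProfileHMM(ProteinMSA(c(a = "WWW", b = "WWW", c = "WWW")),
                        name = "w")
  v <- viterbiHit(m1, "AAWWWAAWWWAA")
  expect_equal(v$env_start, 2L)
  expect_equal(v$env_end, 5L)
})

test_that("gumbel calibration recovers known parameters and is self-consistent", {
  set.seed(31)
  x <- 5 - log(-log(runif(5000))) / 0.7      # Gumbel(mu = 5, lambda = 0.7)
  fit <- ftszprov:::gumbelFit(x)
  expect_lt(abs(fit$mu - 5), 0.1)
  expect_lt(abs(fit$lambda - 0.7), 0.05)

  set.seed(32)
  h <- calibrateHMM(buildProfileHMM(familyMsa(6, 50), name = "cal"),
                    nRandom = 1000, seed = 33)
  expect_false(is.na(h@lambda))
  # held-out nulls: expected 1 hit at E <= 1 for db_size = n
  set.seed(34)
  nulls <- setNames(vapply(1:1000, function(i)
    randSeq(50, backgroundFrequencies()), character(1)),
    paste0("n", 1:1000))
  tab <- searchHMM(h, nulls)
  expect_lte(sum(tab$evalue <= 1), 5)

  # E-values double with db size and decrease in bits
  expect_equal(hmmEvalue(h, 10, 2000), 2 * hmmEvalue(h, 10, 1000))
  bits <- seq(-5, 30, by = 1)
  expect_true(all(diff(hmmEvalue(h, bits, 100)) < 0))

  expect_error(ftszprov:::gumbelFit(rep(1, 200)), "calibration-error")
  expect_error(calibrateHMM(buildProfileHMM(familyMsa(4, 30)),
                            nRandom = 50), "invalid-argument")
})

test_that("search returns one best hit per target, sorted, thresholded", {
  set.seed(41)
  msa <- familyMsa(6, 45, noise = 0.1)
  h <- calibrateHMM(buildProfileHMM(msa, name = "srch"), nRandom = 500,
                    seed = 42)
  members <- setNames(msaRows(msa), names(msa))
  decoys <- setNames(vapply(1:30, function(i)
    randSeq(45, backgroundFrequencies()), character(1)),
    paste0("d", 1:30))
  db <- c(members, decoys)
  all <- searchHMM(h, db)                       # no threshold
  expect_equal(nrow(all), length(db))
  expect_true(!is.unsorted(all$evalue))
  hits <- searchHMM(h, db, evalueMax = 1e-3)
  expect_true(all(names(members) %in% hits$target))
  expect_gt(median(all$evalue[all$target %in% names(decoys)]), 1)
  expect_error(searchHMM(buildProfileHMM(msa), db), "state-error")
})

test_that("plain-text model files round-trip to 12 significant digits", {
  set.seed(51)
  h <- calibrateHMM(buildProfileHMM(randMsa(5, 18, gapFrac = 0.15),
                                    name = "rt"),
                    nRandom = 300, seed = 52)
  f <- tempfile(fileext = ".hmm")
  writeHMMFile(h, f)
  h2 <- readHMMFile(f)
  expect_equal(h2@name, h@name)
  expect_equal(h2@match, h@match, tolerance = 1e-11)
  expect_equal(h2@trans, h@trans, tolerance = 1e-11)
  expect_equal(h2@mu, h@mu, tolerance = 1e-11)
  expect_equal(h2@lambda, h@lambda, tolerance = 1e-11)
  # scores agree through the round trip
  s <- randSeq(25)
  expect_equal(forwardBits(h2, s), forwardBits(h, s), tolerance = 1e-9)
})
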