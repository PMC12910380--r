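test_that("shannonEntropy matches closed forms", {
  expect_equal(shannonEntropy(c(A = 10)), 0)
  expect_equal(shannonEntropy(c(A = 5, C = 5)), 1)
  expect_equal(shannonEntropy(c(A = 2, C = 1, D = 1)), 1.5)
  u <- rep(1, 20); names(u) <- AA20
  expect_equal(shannonEntropy(u), log2(20))
  expect_equal(shannonEntropy(c(A = 1)), 0)    # low support
  expect_equal(shannonEntropy(numeric(0)), 0)  # empty column
  expect_error(shannonEntropy(c(A = -1)), class = "teao_bounds_error")
})

test_that("global profile matches per-column brute force", {
  set.seed(30)
  fx <- simulateMsa(nSubfamilies = 3, sequencesPerSubfamily = 5,
                    nColumns = 30,
                    columnClasses = sample(
                      c("conserved", "subfamily_specific", "random", "gappy"),
                      30, replace = TRUE),
                    substitutionNoise = 0.08, seed = 77)
  m <- do.call(rbind, strsplit(unname(as.character(fx$msa)), ""))
  h <- globalEntropyProfile(fx$msa)
  expect_equal(h, apply(m, 2, oracleEntropy))
  expect_true(all(h >= 0 & h <= log2(20)))

  # identical rows -> all-zero profile
  same <- ProteinMSA(c(a = "MKVL", b = "MKVL", c = "MKVL"))
  expect_equal(globalEntropyProfile(same), rep(0, 4))
})

test_that("level averages behave at the chain ends and in the 50/50 case", {
  fx <- simulateMsa(nSubfamilies = 2, sequencesPerSubfamily = 4,
                    nColumns = 20, seed = 5)
  msa <- fx$msa
  ids <- seqIds(msa)
  one <- setNames(rep(1L, length(ids)), ids)
  singles <- setNames(seq_along(ids), ids)
  expect_equal(levelAverageProfile(msa, one), globalEntropyProfile(msa))
  expect_equal(levelAverageProfile(msa, singles), rep(0, nColumns(msa)))

  # two equal subgroups, each conserved on its own residue: average 0,
  # global exactly 1 bit
  msa2 <- ProteinMSA(c(a1 = "A", a2 = "A", b1 = "C", b2 = "C"))
  grp <- c(a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L)
  expect_equal(globalEntropyProfile(msa2), 1)
  expect_equal(levelAverageProfile(msa2, grp), 0)

  expect_error(levelAverageProfile(msa, c(x = 1L, y = 2L)),
               class = "teao_consistency_error")
})

test_that("teaoProfile level matrix matches direct per-level computation", {
  fx <- simulateMsa(nSubfamilies = 3, sequencesPerSubfamily = 4,
                    nColumns = 25, substitutionNoise = 0.05, seed = 42)
  msa <- fx$msa
  ps <- treeLevels(upgmaTree(pairwiseDistance(msa)))
  prof <- teaoProfile(msa, ps, levels = "all")
  for (k in c(1, 2, 5, nSequences(msa))) {
    expect_equal(hLevel(prof)[k, ],
                 levelAverageProfile(msa, partitionAt(ps, k)),
                 tolerance = 1e-12)
  }
  expect_equal(hLevel(prof)[1, ], hGlobal(prof))
  expect_equal(hAverage(prof), colMeans(hLevel(prof)))
})

test_that("identical alignments give conservation 1, specificity 0", {
  msa <- ProteinMSA(c(a = "MKVL", b = "MKVL", c = "MKVL"))
  ps <- treeLevels(upgmaTree(pairwiseDistance(msa)))
  prof <- teaoProfile(msa, ps)
  expect_equal(hGlobal(prof), rep(0, 4))
  expect_equal(hAverage(prof), rep(0, 4))
  expect_equal(conservation(prof), rep(1, 4))
  expect_equal(specificity(prof), rep(0, 4))
})

test_that("averaged entropy is concave and monotone along refinement", {
  set.seed(60)
  for (seed in 1:6) {
    fx <- simulateMsa(nSubfamilies = sample(2:4, 1),
                      sequencesPerSubfamily = sample(3:6, 1),
                      nColumns = 20,
                      columnClasses = sample(
                        c("conserved", "subfamily_specific", "random",
                          "gappy"), 20, replace = TRUE),
                      substitutionNoise = runif(1, 0, 0.1), seed = seed)
    msa <- fx$msa
    prof <- teaoProfile(msa, treeLevels(upgmaTree(pairwiseDistance(msa))),
                        levels = "all")
    expect_true(all(hAverage(prof) <= hGlobal(prof) + 1e-9))
    lv <- hLevel(prof)
    expect_true(all(diff(lv) <= 1e-9))  # non-increasing in k, per column
  }
})

test_that("profiles are invariant to row and column permutations", {
  fx <- simulateMsa(nSubfamilies = 3, sequencesPerSubfamily = 4,
                    nColumns = 15, seed = 8)
  msa <- fx$msa
  ps <- treeLevels(upgmaTree(pairwiseDistance(msa)))
  prof <- teaoProfile(msa, ps)

  # same partitions, permuted sequence order: identical profile
  set.seed(2)
  rows <- sample(nSequences(msa))
  msaR <- msa[rows]
  profR <- teaoProfile(msaR, ps)
  expect_equal(hGlobal(profR), hGlobal(prof))
  expect_equal(hAverage(profR), hAverage(prof), tolerance = 1e-12)

  cols <- sample(nColumns(msa))
  seqs <- vapply(strsplit(as.character(msa), ""),
                 function(ch) paste(ch[cols], collapse = ""), "")
  msaC <- ProteinMSA(seqs)
  profC <- teaoProfile(msaC, treeLevels(upgmaTree(pairwiseDistance(msaC))))
  expect_equal(hGlobal(profC), hGlobal(prof)[cols])
  expect_equal(specificity(profC), specificity(prof)[cols],
               tolerance = 1e-12)
})

test_that("planted subfamily-specific columns get the top specificity", {
  fx <- simulateMsa(nSubfamilies = 3, sequencesPerSubfamily = 5,
                    nColumns = 40, seed = 19)
  msa <- fx$msa
  prof <- teaoProfile(msa, treeLevels(upgmaTree(pairwiseDistance(msa))))
  specCols <- which(fx$truth$class == "subfamily_specific")
  consCols <- which(fx$truth$class == "conserved")
  ranked <- order(-specificity(prof))
  expect_setequal(ranked[seq_along(specCols)], specCols)
  expect_equal(conservation(prof)[consCols], rep(1, length(consCols)))
})

test_that("gap handling mode changes the distribution as documented", {
  msa <- ProteinMSA(c(a = "A-", b = "A-", c = "AC", d = "AC"))
  # column 2: default ignores gaps -> single residue, H = 0
  expect_equal(globalEntropyProfile(msa)[2], 0)
  # gap-as-symbol: 50/50 gap vs C -> 1 bit
  expect_equal(globalEntropyProfile(msa, gapAsSymbol = TRUE)[2], 1)
  ps <- treeLevels(upgmaTree(pairwiseDistance(msa)))
  prof <- teaoProfile(msa, ps, gapAsSymbol = TRUE)
  expect_equal(prof@normalizer, log2(21))
})

test_that("profile table lines up columns, reference numbering and flags", {
  msa <- ProteinMSA(c(r = "AC-D", s = "ACAD", t = "GCAD"))
  ps <- treeLevels(upgmaTree(pairwiseDistance(msa)))
  prof <- teaoProfile(msa, ps)
  map <- mapReferencePositions(msa, "r")
  tab <- profileTable(prof, map = map,
                      properties = propertySdProfile(msa))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$ref_residue, c(1L, 2L, NA, 3L))
  expect_equal(tab$h_global, hGlobal(prof))
  expect_named(tab, c("column", "ref_residue", "h_global", "h_avg",
                      "conservation", "specificity", "gap_fraction",
                      "n_distinct", "low_support", "z1_sd", "z2_sd",
                      "z3_sd"))
})
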