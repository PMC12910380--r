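test_that("p-distance uses pairwise-complete columns", {
  msa <- ProteinMSA(c(a = "AAAA", b = "AAAA"))
  expect_equal(pairwiseDistance(msa)["a", "b"], 0)

  msa2 <- ProteinMSA(c(a = "AAAA", b = "AAAC"))
  expect_equal(pairwiseDistance(msa2)["a", "b"], 0.25)

  # comparable columns are {1, 3} only; both match -> 0
  msa3 <- ProteinMSA(c(a = "A-CD", b = "AAC-"))
  expect_equal(pairwiseDistance(msa3)["a", "b"], 0)

  # ambiguity codes are excluded like gaps
  msa4 <- ProteinMSA(c(a = "AXCD", b = "AACD"))
  expect_equal(pairwiseDistance(msa4)["a", "b"], 0)

  # no comparable columns: distance 1 with a warning
  msa5 <- ProteinMSA(c(a = "AA--", b = "--CC", c = "AACC"))
  expect_warning(d5 <- pairwiseDistance(msa5), "no comparable column")
  expect_equal(d5["a", "b"], 1)
  expect_equal(diag(d5), c(a = 0, b = 0, c = 0))
  expect_true(isSymmetric(d5))
})

test_that("UPGMA reproduces the 3-taxon hand computation", {
  d <- matrix(c(0, 2, 4,
                2, 0, 4,
                4, 4, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgmaTree(d)
  expect_equal(mergeHeights(tr), c(1, 2))
  ps <- treeLevels(tr)
  expect_equal(canonicalPartition(partitionAt(ps, 2)), c("A|B", "C"))
  expect_equal(writeNewick(tr), "((A:1,B:1):1,C:2);")

  # two leaves merge at d/2
  d2 <- matrix(c(0, 0.2, 0.2, 0), 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- upgmaTree(d2)
  expect_equal(mergeHeights(tr2), 0.1)
  expect_equal(writeNewick(tr2), "(A:0.1,B:0.1);")
})

test_that("invalid distance matrices are rejected", {
  d <- matrix(c(0, NA, NA, 0), 2)
  expect_error(upgmaTree(d), class = "teao_matrix_error")
  d2 <- matrix(c(0, -0.1, -0.1, 0), 2)
  expect_error(upgmaTree(d2), class = "teao_matrix_error")
  expect_error(upgmaTree(matrix(0, 1, 1)), class = "teao_size_error")
})

test_that("production UPGMA equals the brute-force oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    d <- randomDistMatrix(n)
    tr <- upgmaTree(d)
    ps <- treeLevels(tr)
    or <- oracleUpgma(d)
    expect_equal(mergeHeights(tr), or$heights, tolerance = 1e-12)
    for (k in seq_len(n)) {
      expect_equal(canonicalPartition(partitionAt(ps, k)),
                   or$partitions[[k]])
    }
  }
})

test_that("UPGMA heights agree with average-linkage hclust", {
  set.seed(7)
  d <- randomDistMatrix(10)
  tr <- upgmaTree(d)
  hc <- stats::hclust(as.dist(d), method = "average")
  # hclust merges at the full average distance; we merge at half of it
  expect_equal(mergeHeights(tr), hc$height / 2, tolerance = 1e-12)
})

test_that("cophenetic distances are ultrametric and Newick round-trips", {
  set.seed(55)
  d <- randomDistMatrix(7)
  tr <- upgmaTree(d)
  coph <- copheneticMatrix(tr)
  n <- nrow(coph)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(coph[i, j], max(coph[i, k], coph[j, k]) + 1e-12)
  }
  # independent Newick reader recovers the same leaf-to-leaf distances
  ph <- ape::read.tree(text = writeNewick(tr))
  expect_setequal(ph$tip.label, seqIds(tr))
  apeCoph <- ape::cophenetic.phylo(ph)[rownames(coph), colnames(coph)]
  expect_equal(unname(apeCoph), unname(coph), tolerance = 1e-6)
})

test_that("labels with Newick metacharacters are quoted", {
  d <- matrix(c(0, 0.2, 0.2, 0), 2,
              dimnames = list(c("a b(c)", "d:e"), c("a b(c)", "d:e")))
  nwk <- writeNewick(upgmaTree(d))
  expect_match(nwk, "'a b(c)'", fixed = TRUE)
  ph <- ape::read.tree(text = nwk)
  # ape retains the quoting characters; strip them before comparing
  expect_setequal(gsub("^'|'$", "", ph$tip.label), c("a b(c)", "d:e"))
})

test_that("tree levels form a strict refinement chain", {
  set.seed(21)
  d <- randomDistMatrix(9)
  ps <- treeLevels(upgmaTree(d))
  n <- 9
  expect_equal(unname(partitionAt(ps, 1)), rep(1L, n))
  expect_equal(length(unique(partitionAt(ps, n))), n)
  for (k in seq_len(n - 1)) {
    coarse <- partitionAt(ps, k)
    fine <- partitionAt(ps, k + 1)
    # each fine subgroup maps into exactly one coarse subgroup
    expect_true(all(tapply(coarse, fine,
                           function(v) length(unique(v))) == 1L))
  }
  expect_error(partitionAt(ps, 0), class = "teao_bounds_error")
})

test_that("partitions are invariant to input record order", {
  # continuous distances: no exact ties, so the clustering is permutation-
  # invariant up to leaf labels
  set.seed(31)
  n <- 8
  d <- randomDistMatrix(n)
  perm <- sample(n)
  dP <- d[perm, perm]
  ps <- treeLevels(upgmaTree(d))
  psP <- treeLevels(upgmaTree(dP))
  for (k in seq_len(n)) {
    expect_equal(canonicalPartition(partitionAt(ps, k)),
                 canonicalPartition(partitionAt(psP, k)))
  }
})
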