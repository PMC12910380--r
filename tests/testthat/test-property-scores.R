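test_that("built-in z-scale table has the documented shape and content", {
  z <- builtinZscales()
  v <- propertyValues(z)
  expect_equal(dim(v), c(20L, 3L))
  expect_setequal(rownames(v), AA20)
  expect_equal(descriptorNames(z), c("z1", "z2", "z3"))
  expect_true(all(is.finite(v)))
  # non-degenerate: every descriptor separates residues
  expect_true(all(apply(v, 2, function(col) length(unique(col)) > 1)))
  # spot values: tryptophan is strongly lipophilic (most negative z1),
  # glycine the least bulky (most negative z2)
  expect_equal(rownames(v)[which.min(v[, "z1"])], "W")
  expect_equal(rownames(v)[which.min(v[, "z2"])], "G")
})

test_that("SD profile matches closed forms", {
  z <- builtinZscales()
  v <- propertyValues(z)

  cons <- ProteinMSA(c(a = "LLL", b = "LLL", c = "LLL"))
  expect_equal(unname(sdMatrix(propertySdProfile(cons, z))),
               matrix(0, 3, 3))

  # n = 2: population SD is |v1 - v2| / 2
  two <- ProteinMSA(c(a = "LK", b = "IK"))
  sd <- sdMatrix(propertySdProfile(two, z))
  expect_equal(unname(sd[1, ]), unname(abs(v["L", ] - v["I", ]) / 2))
  expect_equal(unname(sd[2, ]), c(0, 0, 0))

  # fewer than 2 scored residues: flagged, SD 0
  gappy <- ProteinMSA(c(a = "L-", b = "--", c = "-X"))
  pp <- propertySdProfile(gappy, z)
  expect_equal(lowSupport(pp), c(TRUE, TRUE))
  expect_equal(unname(sdMatrix(pp)), matrix(0, 2, 3))
})

test_that("SD profile matches brute force on random fixtures", {
  set.seed(14)
  fx <- simulateMsa(nSubfamilies = 3, sequencesPerSubfamily = 4,
                    nColumns = 30,
                    columnClasses = sample(
                      c("conserved", "subfamily_specific", "random",
                        "gappy"), 30, replace = TRUE),
                    substitutionNoise = 0.05, seed = 14)
  z <- builtinZscales()
  v <- propertyValues(z)
  m <- do.call(rbind, strsplit(unname(as.character(fx$msa)), ""))
  for (mode in c("occurrence", "distinct")) {
    sd <- sdMatrix(propertySdProfile(fx$msa, z, weighting = mode))
    for (dd in 1:3) {
      expect_equal(sd[, dd],
                   apply(m, 2, oracleSd, values = v[, dd],
                         weighting = mode),
                   tolerance = 1e-12)
    }
  }
})

test_that("SD is order-invariant and equivariant under affine transforms", {
  fx <- simulateMsa(nSubfamilies = 2, sequencesPerSubfamily = 5,
                    nColumns = 15, seed = 23)
  z <- builtinZscales()
  sd <- sdMatrix(propertySdProfile(fx$msa, z))
  set.seed(3)
  perm <- sample(nSequences(fx$msa))
  expect_equal(sdMatrix(propertySdProfile(fx$msa[perm], z)), sd)

  # a*v + b scales the SD column by |a|
  v2 <- propertyValues(z)
  v2[, 1] <- -3 * v2[, 1] + 7
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(residue = rownames(v2), v2), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  z2 <- loadPropertyTable(path)
  sd2 <- sdMatrix(propertySdProfile(fx$msa, z2))
  expect_equal(sd2[, 1], 3 * sd[, 1], tolerance = 1e-12)
  expect_equal(sd2[, 2:3], sd[, 2:3])
})

test_that("duplicating a sequence reweights occurrences as brute force says", {
  msa <- ProteinMSA(c(a = "LIK", b = "IIK", c = "LVK"))
  dup <- ProteinMSA(c(a = "LIK", b = "IIK", c = "LVK", d = "LVK"))
  z <- builtinZscales()
  v <- propertyValues(z)
  m <- do.call(rbind, strsplit(unname(as.character(dup)), ""))
  sd <- sdMatrix(propertySdProfile(dup, z))
  expect_equal(sd[, 1], apply(m, 2, oracleSd, values = v[, 1]))
  # distinct mode ignores the duplication entirely
  expect_equal(sdMatrix(propertySdProfile(dup, z, weighting = "distinct")),
               sdMatrix(propertySdProfile(msa, z, weighting = "distinct")))
})

test_that("custom tables load, validate and round-trip", {
  # single-descriptor table
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(residue = AA20, hydro = seq_len(20) / 10), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- loadPropertyTable(path, name = "hydro")
  expect_equal(ncol(propertyValues(tab)), 1L)

  # missing residue
  bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(residue = AA20[-5], x = 1:19), bad, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(loadPropertyTable(bad), class = "teao_schema_error")
  expect_error(loadPropertyTable(bad), regexp = "F")

  # duplicate residue
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(residue = c(AA20, "A"), x = 1:21), bad2,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadPropertyTable(bad2), class = "teao_schema_error")

  # non-numeric cell with row/column pointer
  bad3 <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(residue = AA20, x = as.character(1:20))
  df$x[7] <- "oops"
  write.table(df, bad3, sep = "\t", quote = FALSE, row.names = FALSE)
  err <- tryCatch(loadPropertyTable(bad3), error = function(e) e)
  expect_s3_class(err, "teao_schema_error")
  expect_match(conditionMessage(err), "'oops' at row 7")

  # write + reload of the builtin equals the builtin
  z <- builtinZscales()
  rt <- withr::local_tempfile(fileext = ".tsv")
  writePropertyTable(z, rt)
  z2 <- loadPropertyTable(rt)
  expect_equal(propertyValues(z2), propertyValues(z))
  expect_equal(descriptorNames(z2), descriptorNames(z))
})
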