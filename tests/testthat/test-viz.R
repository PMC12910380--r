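vizFixture <- function() {
  fx <- simulateMsa(nSubfamilies = 3, sequencesPerSubfamily = 4,
                    nColumns = 30, seed = 6)
  msa <- fx$msa
  tree <- upgmaTree(pairwiseDistance(msa))
  list(msa = msa, tree = tree,
       entropy = teaoProfile(msa, treeLevels(tree)),
       props = propertySdProfile(msa),
       map = suppressMessages(mapReferencePositions(msa)))
}

test_that("panel tables carry exactly the plotted values", {
  v <- vizFixture()
  dat <- panelData(v$msa, v$entropy, properties = v$props, tree = v$tree,
                   panels = c("entropy_lines", "conservation_specificity",
                              "presence_matrix", "variant_counts",
                              "frequency_stack", "zscale_heatmap",
                              "tree_with_divisions",
                              "two_entropies_scatter"))
  expect_equal(dat$entropy_lines$h_global, hGlobal(v$entropy))
  expect_equal(dat$entropy_lines$h_avg, hAverage(v$entropy))
  expect_equal(dat$conservation_specificity$specificity,
               specificity(v$entropy))
  expect_equal(dat$variant_counts$n_distinct, nDistinct(v$entropy))
  expect_equal(dat$two_entropies_scatter$h_avg, hAverage(v$entropy))

  # presence and frequency agree with the column compositions
  for (cc in c(1, 15, 30)) {
    rc <- residueCounts(columnComposition(v$msa, cc))
    pres <- dat$presence_matrix[dat$presence_matrix$column == cc, ]
    expect_equal(pres$present[match(names(rc), pres$residue)],
                 as.integer(rc > 0))
    freq <- dat$frequency_stack[dat$frequency_stack$column == cc, ]
    expect_equal(freq$frequency[match(names(rc), freq$residue)],
                 unname(rc) / nSequences(v$msa))
  }
  expect_equal(matrix(dat$zscale_heatmap$sd, ncol = 3, byrow = TRUE),
               unname(sdMatrix(v$props)))
  expect_equal(dat$tree_with_divisions$height, mergeHeights(v$tree))
})

test_that("an all-identical alignment yields flat panels", {
  msa <- ProteinMSA(c(a = "MKVLA", b = "MKVLA", c = "MKVLA"))
  tree <- upgmaTree(pairwiseDistance(msa))
  prof <- teaoProfile(msa, treeLevels(tree))
  dat <- panelData(msa, prof, properties = propertySdProfile(msa),
                   panels = c("entropy_lines", "variant_counts",
                              "zscale_heatmap"))
  expect_equal(dat$entropy_lines$h_global, rep(0, 5))
  expect_equal(dat$entropy_lines$h_avg, rep(0, 5))
  expect_equal(dat$variant_counts$n_distinct, rep(1L, 5))
  expect_equal(dat$zscale_heatmap$sd, rep(0, 15))
})

test_that("column ranges restrict every table inclusively", {
  v <- vizFixture()
  dat <- panelData(v$msa, v$entropy, properties = v$props,
                   panels = c("entropy_lines", "presence_matrix",
                              "zscale_heatmap"),
                   columnRange = c(5, 25))
  for (tab in dat) {
    expect_equal(sort(unique(tab$column)), 5:25)
  }
  expect_error(panelData(v$msa, v$entropy, columnRange = c(0, 10)),
               class = "teao_bounds_error")
  expect_error(panelData(v$msa, v$entropy, columnRange = c(5, 31)),
               class = "teao_bounds_error")
})

test_that("panel prerequisites and color maps are validated", {
  v <- vizFixture()
  expect_error(panelData(v$msa, v$entropy, panels = "zscale_heatmap"),
               class = "teao_config_error")
  expect_error(panelData(v$msa, v$entropy, panels = "tree_with_divisions"),
               class = "teao_config_error")
  expect_error(panelData(v$msa, v$entropy, panels = "nope"),
               class = "teao_config_error")
  cols <- residueColors()
  expect_length(cols, 20L)
  expect_false(anyDuplicated(cols) > 0)
  badCols <- cols
  badCols[2] <- badCols[1]
  expect_error(renderOverview(v$msa, v$entropy, dir = withr::local_tempdir(),
                              colors = badCols),
               class = "teao_config_error")
})

test_that("renderOverview writes the figure plus one sidecar per panel", {
  v <- vizFixture()
  dir <- withr::local_tempdir()
  paths <- renderOverview(v$msa, v$entropy, properties = v$props,
                          tree = v$tree, map = v$map, dir = dir,
                          format = "png", dpi = 72)
  expect_true(all(file.exists(paths)))
  expect_match(paths[1], "\\.png$")
  expect_length(paths, 8L)  # figure + 7 default panels
  # sidecars reproduce the panelData tables exactly
  sidecar <- read.delim(file.path(dir, "overview_entropy_lines.tsv"))
  expect_equal(sidecar$h_global, hGlobal(v$entropy))

  # panels lacking inputs are dropped quietly when profiles are absent
  paths2 <- renderOverview(v$msa, v$entropy, dir = dir,
                           basename = "plain", format = "pdf")
  expect_length(paths2, 6L)  # no zscale, no tree panel
})
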