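# viz: the multi-panel per-position overview figure and its machine-readable
# sidecar tables. Tests assert on the tables; images are only smoke-tested
# (pixel assertions are brittle).

.ALL_PANELS <- c("entropy_lines", "conservation_specificity",
                 "presence_matrix", "variant_counts", "frequency_stack",
                 "zscale_heatmap", "tree_with_divisions",
                 "two_entropies_scatter")

#' Fixed color map for the 20 standard residues
#'
#' A bijection residue -> color, grouped by physicochemical character
#' (hydrophobic greens/olives, polar blues, acidic reds, basic purples,
#' special-case oranges); chosen for distinguishability, overridable in
#' [renderOverview()].
#'
#' @return Named character vector of 20 hex colors.
#' @export
residueColors <- function() {
  c(A = "#66C2A5", C = "#E6AB02", D = "#D53E4F", E = "#F46D43",
    F = "#1B7837", G = "#B3B3B3", H = "#8DA0CB", I = "#41AB5D",
    K = "#762A83", L = "#006D2C", M = "#A6D854", N = "#3288BD",
    P = "#E78AC3", Q = "#5E4FA2", R = "#9E0142", S = "#80B1D3",
    T = "#2166AC", V = "#74C476", W = "#BF812D", Y = "#35978F")
}

#' Per-panel data tables for the overview figure
#'
#' Exactly the values the figure draws, as data frames -- the testable and
#' reusable surface of the visualization.
#'
#' @param msa A [ProteinMSA-class].
#' @param entropy An [EntropyProfile-class] on the same alignment.
#' @param properties Optional [PropertyProfile-class]
#'   (needed for `zscale_heatmap`).
#' @param tree Optional [UpgmaTree-class] (needed for
#'   `tree_with_divisions`).
#' @param panels Subset of the available panels (see
#'   [renderOverview()]).
#' @param columnRange Optional 1-based closed interval `c(from, to)`
#'   restricting the column axis.
#' @return Named list of data frames, one per requested panel.
#' @export
panelData <- function(msa, entropy, properties = NULL, tree = NULL,
                      panels = setdiff(.ALL_PANELS, "two_entropies_scatter"),
                      columnRange = NULL) {
  bad <- setdiff(panels, .ALL_PANELS)
  if (length(bad)) {
    .teaoStop("teao_config_error", paste0(
      "unknown panel(s): ", paste(bad, collapse = ", ")))
  }
  L <- nColumns(msa)
  if (nColumns(entropy) != L) {
    .teaoStop("teao_consistency_error",
              "entropy profile does not match the alignment")
  }
  if (is.null(columnRange)) {
    columnRange <- c(1L, L)
  }
  columnRange <- as.integer(columnRange)
  if (length(columnRange) != 2L || columnRange[1L] < 1L ||
      columnRange[2L] > L || columnRange[1L] > columnRange[2L]) {
    .teaoStop("teao_bounds_error", sprintf(
      "columnRange must be a closed interval inside 1..%d", L))
  }
  cols <- seq(columnRange[1L], columnRange[2L])
  if ("zscale_heatmap" %in% panels && is.null(properties)) {
    .teaoStop("teao_config_error",
              "zscale_heatmap requested but no property profile given")
  }
  if ("tree_with_divisions" %in% panels && is.null(tree)) {
    .teaoStop("teao_config_error",
              "tree_with_divisions requested but no tree given")
  }

  arr <- .countsArray(.codeMatrix(msa))
  out <- list()
  for (p in panels) {
    out[[p]] <- switch(p,
      entropy_lines = data.frame(
        column = cols,
        h_global = hGlobal(entropy)[cols],
        h_avg = hAverage(entropy)[cols]),
      conservation_specificity = data.frame(
        column = cols,
        conservation = conservation(entropy)[cols],
        specificity = specificity(entropy)[cols]),
      presence_matrix = data.frame(
        column = rep(cols, each = 20L),
        residue = rep(.AA20, length(cols)),
        present = as.integer(arr$counts[, cols] > 0L)),
      variant_counts = data.frame(
        column = cols,
        n_distinct = nDistinct(entropy)[cols]),
      frequency_stack = {
        n <- nSequences(msa)
        data.frame(
          column = rep(cols, each = 20L),
          residue = rep(.AA20, length(cols)),
          frequency = as.numeric(arr$counts[, cols]) / n)
      },
      zscale_heatmap = {
        sd <- sdMatrix(properties)
        dn <- descriptorNames(properties)
        data.frame(
          column = rep(cols, each = length(dn)),
          descriptor = rep(dn, length(cols)),
          sd = as.numeric(t(sd[cols, , drop = FALSE])))
      },
      tree_with_divisions = data.frame(
        merge = seq_along(mergeHeights(tree)),
        height = mergeHeights(tree),
        division = c(mergeHeights(tree)[-1L], NA) / 2 +
          mergeHeights(tree) / 2),
      two_entropies_scatter = data.frame(
        column = cols,
        h_global = hGlobal(entropy)[cols],
        h_avg = hAverage(entropy)[cols]))
  }
  out
}

# ---- drawing helpers (base graphics; deterministic layout) ----

.drawLetters <- function(cols, letters, colors = NULL, side = 3) {
  if (length(cols) > 150L) {
    return(invisible())  # unreadable at that density
  }
  col <- if (is.null(colors)) "black" else colors[letters]
  mtext(letters, side = side, at = cols, line = 0.2, cex = 0.5, col = col)
}

.panelPlot <- function(dat, panel, msa, entropy, properties, tree, colors,
                       refSeq = NULL) {
  cols <- unique(dat$column)          # NULL for the tree panel
  xlim <- if (length(cols)) range(cols) + c(-0.5, 0.5) else NULL
  switch(panel,
    entropy_lines = {
      plot(dat$column, dat$h_global, type = "l", col = "#7A1F2B",
           xlim = xlim, ylim = c(0, maxEntropyBits()), xlab = "",
           ylab = "H (bits)", las = 1)
      lines(dat$column, dat$h_avg, col = "#27598E")
      legend("topright", legend = c("global", "average"), bty = "n",
             col = c("#7A1F2B", "#27598E"), lty = 1, cex = 0.7)
      if (!is.null(refSeq)) {
        .drawLetters(cols, strsplit(refSeq, "")[[1L]][cols])
      }
    },
    conservation_specificity = {
      plot(dat$column, dat$conservation, type = "h", col = "#27598E",
           xlim = xlim, ylim = c(0, 1), xlab = "", ylab = "score", las = 1)
      points(dat$column + 0.25, dat$specificity, type = "h", col = "#C2559C")
      legend("topright", legend = c("conservation", "specificity"),
             bty = "n", col = c("#27598E", "#C2559C"), lty = 1, cex = 0.7)
    },
    presence_matrix = {
      plot.new()
      plot.window(xlim = xlim, ylim = c(0.5, 20.5))
      hit <- dat[dat$present == 1L, ]
      rect(hit$column - 0.5, match(hit$residue, .AA20) - 0.5,
           hit$column + 0.5, match(hit$residue, .AA20) + 0.5,
           col = colors[hit$residue], border = NA)
      axis(2, at = seq_len(20L), labels = .AA20, las = 1, cex.axis = 0.5,
           tick = FALSE)
      axis(1)
      title(ylab = "residue")
      box()
    },
    variant_counts = {
      plot(dat$column, dat$n_distinct, type = "h", col = "grey30",
           xlim = xlim, ylim = c(0, 20), xlab = "", ylab = "# residues",
           las = 1)
    },
    frequency_stack = {
      plot.new()
      plot.window(xlim = xlim, ylim = c(0, 1))
      for (cc in cols) {
        f <- dat$frequency[dat$column == cc]
        names(f) <- dat$residue[dat$column == cc]
        f <- f[f > 0]
        if (!length(f)) next
        tops <- cumsum(f)
        rect(cc - 0.5, c(0, head(tops, -1L)), cc + 0.5, tops,
             col = colors[names(f)], border = NA)
      }
      axis(1)
      axis(2, las = 1)
      title(ylab = "frequency")
      box()
    },
    zscale_heatmap = {
      dn <- unique(dat$descriptor)
      m <- matrix(dat$sd, nrow = length(dn),
                  dimnames = list(dn, NULL))
      image(x = cols, y = seq_along(dn), z = t(m), zlim = c(0, max(m, 1e-9)),
            col = grey(seq(1, 0.2, length.out = 64L)), xlab = "",
            ylab = "", axes = FALSE, xlim = xlim)
      axis(1)
      axis(2, at = seq_along(dn), labels = dn, las = 1, cex.axis = 0.7)
      box()
    },
    tree_with_divisions = {
      h <- asHclust(tree)
      n <- length(h$labels)
      plot.new()
      plot.window(xlim = c(0, max(h$height) * 1.05), ylim = c(0.5, n + 0.5))
      pos <- numeric(2L * n - 1L)         # node -> y position
      pos[seq_len(n)] <- order(h$order)   # leaf i at its display row
      leafY <- pos[seq_len(n)]
      nodeH <- c(numeric(n), h$height)
      for (m in seq_len(n - 1L)) {
        kid <- h$merge[m, ]
        idx <- ifelse(kid < 0L, -kid, n + kid)
        y <- pos[idx]
        x0 <- nodeH[idx]
        segments(x0, y, h$height[m], y)
        segments(h$height[m], y[1L], h$height[m], y[2L])
        pos[n + m] <- mean(y)
      }
      mids <- (h$height[-length(h$height)] + h$height[-1L]) / 2
      abline(v = mids, col = "grey70", lty = 3)
      axis(1)
      title(xlab = "merge height")
      box()
    },
    two_entropies_scatter = {
      plot(dat$h_global, dat$h_avg, pch = 16, cex = 0.6, col = "grey25",
           xlab = "global H (bits)", ylab = "average H (bits)", las = 1,
           xlim = c(0, maxEntropyBits()), ylim = c(0, maxEntropyBits()))
      abline(0, 1, col = "grey70", lty = 2)
    })
}

#' Render the multi-panel per-position overview figure
#'
#' Draws the requested panels stacked on a shared alignment-column axis:
#' entropy lines (global maroon, averaged blue) with the reference sequence
#' lettered above; conservation/specificity bars; the residue presence
#' matrix (white = absent); distinct-residue counts; per-residue frequency
#' stacks; the z-scale standard-deviation heatmap (darker = more variable)
#' with the consensus sequence below the final profile panel; and the UPGMA
#' dendrogram with grey division lines between merge heights. A
#' two-entropies scatter (global vs averaged H per column) is available but
#' off by default. Every panel's plotted values are also written as a
#' sidecar TSV; the figure contains nothing the tables do not.
#'
#' @inheritParams panelData
#' @param map Optional [PositionMap-class]; its reference sequence is
#'   lettered above the first panel.
#' @param dir Output directory (created if needed).
#' @param basename Stem for all output files.
#' @param format `"pdf"`, `"png"` or `"svg"`.
#' @param dpi Raster resolution for `"png"`.
#' @param colors Residue color map (bijection over the 20 residues;
#'   default [residueColors()]).
#' @return Character vector of written file paths (figure first, then one
#'   TSV per panel), invisibly.
#' @export
renderOverview <- function(msa, entropy, properties = NULL, tree = NULL,
                           map = NULL,
                           panels = setdiff(.ALL_PANELS,
                                            "two_entropies_scatter"),
                           columnRange = NULL, dir = ".",
                           basename = "overview", format = c("pdf", "png", "svg"),
                           dpi = 150, colors = residueColors()) {
  format <- match.arg(format)
  if (!setequal(names(colors), .AA20) || anyDuplicated(colors)) {
    .teaoStop("teao_config_error",
              "colors must be a bijection over the 20 standard residues")
  }
  if (is.null(properties)) {
    panels <- setdiff(panels, "zscale_heatmap")
  }
  if (is.null(tree)) {
    panels <- setdiff(panels, "tree_with_divisions")
  }
  dat <- panelData(msa, entropy, properties = properties, tree = tree,
                   panels = panels, columnRange = columnRange)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  figPath <- file.path(dir, paste0(basename, ".", format))
  npanel <- length(panels)
  hPer <- 1.6
  switch(format,
         pdf = pdf(figPath, width = 9, height = hPer * npanel + 1),
         png = png(figPath, width = 9, height = hPer * npanel + 1,
                   units = "in", res = dpi),
         svg = svg(figPath, width = 9, height = hPer * npanel + 1))
  on.exit(dev.off(), add = TRUE)
  op <- par(mfrow = c(npanel, 1L), mar = c(2.2, 4, 1.2, 1), mgp = c(2, 0.6, 0))
  on.exit(par(op), add = TRUE)
  refSeq <- if (!is.null(map)) {
    as.character(msa)[[referenceId(map)]]
  } else {
    NULL
  }
  profilePanels <- setdiff(panels, c("tree_with_divisions",
                                     "two_entropies_scatter"))
  lastProfile <- if (length(profilePanels)) {
    profilePanels[length(profilePanels)]
  } else {
    NA_character_
  }
  for (p in panels) {
    .panelPlot(dat[[p]], p, msa, entropy, properties, tree, colors,
               refSeq = if (p == panels[1L]) refSeq else NULL)
    mtext(p, side = 3, adj = 0, line = 0.1, cex = 0.6, font = 2)
    if (identical(p, lastProfile)) {
      cols <- unique(dat[[p]]$column)
      cons <- strsplit(consensusSequence(msa), "")[[1L]][cols]
      .drawLetters(cols, cons, side = 1)
    }
  }
  paths <- figPath
  for (p in panels) {
    tp <- file.path(dir, paste0(basename, "_", p, ".tsv"))
    .writeTsv(dat[[p]], tp)
    paths <- c(paths, tp)
  }
  invisible(paths)
}
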