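# entropy: per-column Shannon entropy, globally and within subgroups, and the
# two-entropies (TEA-O) averaged profile with conservation/specificity scores.

#' Shannon entropy of a residue distribution
#'
#' `H = -sum(p_a * log2(p_a))` over residues with count > 0, in bits.
#' Gaps and ambiguity codes never enter the distribution. Columns with at
#' most one counted residue have entropy 0 (low-support convention, flagged
#' downstream rather than propagating NaN).
#'
#' @param x A [ResidueCounts-class] or a non-negative numeric count vector.
#' @return Entropy in bits.
#' @examples
#' shannonEntropy(c(A = 5, C = 5))       # 1
#' shannonEntropy(c(A = 2, C = 1, D = 1))  # 1.5
#' @export
setGeneric("shannonEntropy", function(x) standardGeneric("shannonEntropy"))

#' @rdname shannonEntropy
#' @export
setMethod("shannonEntropy", "ResidueCounts",
          function(x) .entropyOfCounts(x@counts))

#' @rdname shannonEntropy
#' @export
setMethod("shannonEntropy", "numeric", function(x) {
  if (any(x < 0)) {
    .teaoStop("teao_bounds_error", "counts must be non-negative")
  }
  .entropyOfCounts(x)
})

# 20 x L counts (plus gap row in gap-as-symbol mode)
.globalCounts <- function(codes, gapAsSymbol = FALSE) {
  arr <- .countsArray(codes)
  cnt <- arr$counts
  if (gapAsSymbol) {
    cnt <- rbind(cnt, `-` = arr$gaps)
  }
  cnt
}

#' Global per-column entropy profile
#'
#' [shannonEntropy()] applied to every column's composition.
#'
#' @param x A [ProteinMSA-class].
#' @param gapAsSymbol Treat the gap as a 21st symbol instead of excluding it
#'   (default `FALSE`; exclusion avoids inflated entropy at ragged edges).
#' @return Numeric vector of length `nColumns(x)`, in bits.
#' @export
globalEntropyProfile <- function(x, gapAsSymbol = FALSE) {
  .entropyColumns(.globalCounts(.codeMatrix(x), gapAsSymbol))
}

#' Subgroup-averaged entropy at one partition level
#'
#' For each column, the size-weighted mean over subgroups g of the
#' within-subgroup entropy: `sum_g (n_g / N) * H_g[c]`. Size-weighting makes
#' the average provably bounded by the pooled (global) entropy.
#'
#' @param x A [ProteinMSA-class].
#' @param partition Named integer vector assigning every sequence identifier
#'   to a subgroup (as returned by [partitionAt()]).
#' @param gapAsSymbol See [globalEntropyProfile()].
#' @return Numeric vector of length `nColumns(x)`, in bits.
#' @export
levelAverageProfile <- function(x, partition, gapAsSymbol = FALSE) {
  ids <- seqIds(x)
  if (is.null(names(partition)) || !setequal(names(partition), ids) ||
      length(partition) != length(ids)) {
    .teaoStop("teao_consistency_error",
              "partition must cover exactly the alignment identifiers")
  }
  codes <- .codeMatrix(x)
  g <- partition[ids]
  N <- nrow(codes)
  acc <- numeric(ncol(codes))
  for (rows in split(seq_len(N), g)) {
    if (length(rows) < 2L) {
      next  # a single sequence has entropy 0 at every column
    }
    cnt <- .globalCounts(codes[rows, , drop = FALSE], gapAsSymbol)
    acc <- acc + (length(rows) / N) * .entropyColumns(cnt)
  }
  acc
}

# which partition levels enter the across-level average
.levelIndices <- function(n, levels) {
  if (is.numeric(levels)) {
    lv <- sort(unique(as.integer(levels)))
    if (!length(lv) || anyNA(lv) || min(lv) < 1L || max(lv) > n) {
      .teaoStop("teao_bounds_error",
                sprintf("levels must be a subset of 1..%d", n))
    }
    return(lv)
  }
  switch(match.arg(levels, c("coarse", "all", "trimmed")),
         coarse = seq_len(max(2L, min(n, ceiling(sqrt(n))))),
         all = seq_len(n),
         trimmed = if (n > 2L) 2L:(n - 1L) else seq_len(n))
}

# Subgroup-averaged entropy for every level of a refinement chain.
# Counts are additive along the chain, so each internal subgroup is scored
# exactly once: O(N * L * alphabet) overall instead of O(N^2 * L).
.levelEntropyMatrix <- function(codes, lev, gapAsSymbol = FALSE) {
  N <- nrow(codes)
  L <- ncol(codes)
  Hlev <- matrix(0, N, L)
  prev <- lev[N, ]
  counts <- vector("list", N)
  hgrp <- vector("list", N)
  szgrp <- integer(N)
  for (i in seq_len(N)) {
    g <- prev[i]
    counts[[g]] <- .globalCounts(codes[i, , drop = FALSE], gapAsSymbol)
    hgrp[[g]] <- numeric(L)          # singleton entropy is 0
    szgrp[g] <- 1L
  }
  S <- numeric(L)                    # running size-weighted entropy sum
  # Hlev[N, ] stays 0: the singleton level
  for (k in seq(N - 1L, 1L)) {
    cur <- lev[k, ]
    sp <- split(seq_len(N), cur)
    newCounts <- vector("list", k)
    newH <- vector("list", k)
    newSz <- integer(k)
    for (g in seq_len(k)) {
      children <- unique(prev[sp[[g]]])
      if (length(children) == 1L) {
        c1 <- children
        newCounts[[g]] <- counts[[c1]]
        newH[[g]] <- hgrp[[c1]]
        newSz[g] <- szgrp[c1]
      } else {
        for (ch in children) {
          S <- S - (szgrp[ch] / N) * hgrp[[ch]]
        }
        cnt <- Reduce(`+`, counts[children])
        h <- .entropyColumns(cnt)
        sz <- sum(szgrp[children])
        S <- S + (sz / N) * h
        newCounts[[g]] <- cnt
        newH[[g]] <- h
        newSz[g] <- sz
      }
    }
    counts <- newCounts
    hgrp <- newH
    szgrp <- newSz
    prev <- cur
    Hlev[k, ] <- S
  }
  Hlev
}

#' Two-entropies (TEA-O) profile
#'
#' Computes, per alignment column: the global Shannon entropy; the
#' size-weighted within-subgroup entropy at every tree level; their
#' unweighted average across the selected levels (`hAvg`); and the derived
#' scores `conservation = 1 - hGlobal/log2(A)` and
#' `specificity = (hGlobal - hAvg)/log2(A)` where A is the alphabet size.
#' Columns that are variable overall but conserved within subgroups score
#' high specificity.
#'
#' @param x A [ProteinMSA-class].
#' @param partitions A [PartitionSet-class] from [treeLevels()] over the
#'   same alignment.
#' @param levels Which tree levels enter the across-level average:
#'   `"coarse"` (the default, levels 1..ceiling(sqrt(N)): subgroup
#'   structure at the scale where subgroups still hold several sequences;
#'   deeper levels are dominated by near-singleton groups whose entropy is
#'   trivially 0 and wash out the subfamily signal), `"all"` (1..N),
#'   `"trimmed"` (2..N-1), or an explicit integer vector of levels.
#' @param gapAsSymbol See [globalEntropyProfile()].
#' @return An [EntropyProfile-class]. The `hLevel` slot always holds all N
#'   levels regardless of `levels`.
#' @export
teaoProfile <- function(x, partitions, levels = "coarse",
                        gapAsSymbol = FALSE) {
  ids <- seqIds(x)
  if (!setequal(seqIds(partitions), ids) ||
      length(seqIds(partitions)) != length(ids)) {
    .teaoStop("teao_consistency_error",
              "partitions must cover exactly the alignment identifiers")
  }
  codes <- .codeMatrix(x)
  N <- nrow(codes)
  lev <- partitions@levels[, match(ids, partitions@ids), drop = FALSE]
  arr <- .countsArray(codes)
  globalCnt <- if (gapAsSymbol) rbind(arr$counts, `-` = arr$gaps) else arr$counts
  hG <- .entropyColumns(globalCnt)
  Hlev <- .levelEntropyMatrix(codes, lev, gapAsSymbol)
  used <- .levelIndices(N, levels)
  hA <- colMeans(Hlev[used, , drop = FALSE])
  norm <- log2(nrow(globalCnt))
  clamp <- function(v) pmin(pmax(v, 0), 1)
  new("EntropyProfile",
      hGlobal = hG,
      hLevel = Hlev,
      hAvg = hA,
      conservation = clamp(1 - hG / norm),
      specificity = clamp((hG - hA) / norm),
      gapFraction = arr$gaps / N,
      nDistinct = as.integer(colSums(arr$counts > 0L)),
      lowSupport = colSums(globalCnt) <= 1,
      levelsUsed = as.integer(used),
      normalizer = norm)
}

#' @rdname EntropyProfile-class
#' @export
setMethod("hGlobal", "EntropyProfile", function(x) x@hGlobal)

#' @rdname EntropyProfile-class
#' @export
setMethod("hAverage", "EntropyProfile", function(x) x@hAvg)

#' @rdname EntropyProfile-class
#' @export
setMethod("hLevel", "EntropyProfile", function(x) x@hLevel)

#' @rdname EntropyProfile-class
#' @export
setMethod("conservation", "EntropyProfile", function(x) x@conservation)

#' @rdname EntropyProfile-class
#' @export
setMethod("specificity", "EntropyProfile", function(x) x@specificity)

#' @rdname EntropyProfile-class
#' @export
setMethod("gapFraction", "EntropyProfile", function(x) x@gapFraction)

#' @rdname EntropyProfile-class
#' @export
setMethod("nDistinct", "EntropyProfile", function(x) x@nDistinct)

#' @rdname EntropyProfile-class
#' @export
setMethod("lowSupport", "EntropyProfile", function(x) x@lowSupport)

#' @rdname EntropyProfile-class
#' @export
setMethod("nColumns", "EntropyProfile", function(x) length(x@hGlobal))

setMethod("show", "EntropyProfile", function(object) {
  cat(sprintf(paste0(
    "EntropyProfile: %d columns, %d levels (%d used for hAvg)\n",
    "  hGlobal [%.3f, %.3f] bits; max specificity %.3f\n"),
    nColumns(object), nrow(object@hLevel), length(object@levelsUsed),
    min(object@hGlobal), max(object@hGlobal), max(object@specificity)))
})

#' Per-position profile table
#'
#' Joins the entropy profile, optional reference numbering and optional
#' property profile into one data frame (one row per alignment column), the
#' package's main tabular output.
#'
#' @param profile An [EntropyProfile-class].
#' @param map Optional [PositionMap-class] supplying reference residue
#'   numbers.
#' @param properties Optional [PropertyProfile-class]; its standard
#'   deviations are appended as `<descriptor>_sd` columns.
#' @return A data.frame.
#' @export
profileTable <- function(profile, map = NULL, properties = NULL) {
  L <- nColumns(profile)
  df <- data.frame(
    column = seq_len(L),
    ref_residue = if (is.null(map)) NA_integer_ else columnToResidue(map),
    h_global = hGlobal(profile),
    h_avg = hAverage(profile),
    conservation = conservation(profile),
    specificity = specificity(profile),
    gap_fraction = gapFraction(profile),
    n_distinct = nDistinct(profile),
    low_support = lowSupport(profile))
  if (!is.null(properties)) {
    sd <- sdMatrix(properties)
    if (nrow(sd) != L) {
      .teaoStop("teao_consistency_error",
                "property profile has a different number of columns")
    }
    colnames(sd) <- paste0(descriptorNames(properties), "_sd")
    df <- cbind(df, as.data.frame(sd))
  }
  df
}
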