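# Deterministic UPGMA with reproducible tie-breaking.
#
# The tree is rebuilt identically regardless of platform or input record
# permutation (up to leaf relabelling): at every step the pair of clusters
# with the minimal size-weighted average distance merges, and exact ties are
# resolved by the lexicographically smallest pair of founding indices (the
# smallest original leaf index contained in each cluster).

#' Build a UPGMA tree from a distance matrix
#'
#' Size-weighted average-linkage agglomeration: the pair of clusters with
#' minimal between-cluster average distance merges at height equal to half
#' that distance, so the cophenetic distance between two leaves equals the
#' average distance at which their clusters merged. The average distances
#' are maintained with the Lance-Williams update
#' `D(i+j, k) = (n_i D(i,k) + n_j D(j,k)) / (n_i + n_j)`.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal;
#'   rownames become the leaf labels.
#' @return An [UpgmaTree-class].
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- upgmaTree(d)
#' mergeHeights(tr)  # 1 2
#' @export
upgmaTree <- function(d) {
  .checkDistanceMatrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) {
    labels <- as.character(seq_len(n))
  }
  D <- unname(d)
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  founding <- seq_len(n)
  code <- -seq_len(n)            # hclust convention
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (m in seq_len(n - 1L)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    minv <- min(sub)
    hits <- which(sub == minv, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    # tie-break on the founding-index pair, lexicographically
    fi <- founding[act[hits[, 1L]]]
    fj <- founding[act[hits[, 2L]]]
    lo <- pmin(fi, fj)
    hi <- pmax(fi, fj)
    pick <- order(lo, hi)[1L]
    i <- act[hits[pick, 1L]]
    j <- act[hits[pick, 2L]]
    if (founding[j] < founding[i]) {
      tmp <- i; i <- j; j <- tmp
    }
    height[m] <- minv / 2
    merge[m, ] <- c(code[i], code[j])
    # Lance-Williams average-linkage update, new cluster kept in slot i
    others <- act[act != i & act != j]
    if (length(others)) {
      newd <- (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
      D[i, others] <- newd
      D[others, i] <- newd
    }
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    founding[i] <- min(founding[i], founding[j])
    code[i] <- m
  }
  new("UpgmaTree", labels = labels, merge = merge, height = height,
      order = .leafOrder(merge, n))
}

# left-to-right leaf order (iterative postorder; avoids deep recursion)
.leafOrder <- function(merge, n) {
  out <- integer(0L)
  stack <- nrow(merge)          # root merge row
  while (length(stack)) {
    nodeId <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (nodeId < 0L) {
      out <- c(out, -nodeId)
    } else {
      # push right child first so the left child is emitted first
      stack <- c(stack, merge[nodeId, 2L], merge[nodeId, 1L])
    }
  }
  out
}

#' @rdname UpgmaTree-class
#' @export
setMethod("mergeHeights", "UpgmaTree", function(x) x@height)

#' @rdname UpgmaTree-class
#' @export
setMethod("nSequences", "UpgmaTree", function(x) length(x@labels))

#' @rdname UpgmaTree-class
#' @export
setMethod("seqIds", "UpgmaTree", function(x) x@labels)

#' @rdname UpgmaTree-class
#' @export
setMethod("asHclust", "UpgmaTree", function(x) {
  structure(list(merge = x@merge, height = x@height, order = x@order,
                 labels = x@labels, method = "upgma",
                 dist.method = "p-distance"),
            class = "hclust")
})

setMethod("show", "UpgmaTree", function(object) {
  cat(sprintf("UpgmaTree: %d leaves, %d merges, root height %.4g\n",
              length(object@labels), nrow(object@merge),
              max(object@height)))
})

# leaf index sets below each merge row
.mergeLeafSets <- function(merge) {
  sets <- vector("list", nrow(merge))
  for (m in seq_len(nrow(merge))) {
    kids <- merge[m, ]
    sets[[m]] <- c(if (kids[1L] < 0L) -kids[1L] else sets[[kids[1L]]],
                   if (kids[2L] < 0L) -kids[2L] else sets[[kids[2L]]])
  }
  sets
}

#' Cophenetic distance matrix of a UPGMA tree
#'
#' `coph(i, j)` is twice the height of the lowest merge joining leaves i and
#' j, i.e. the between-cluster average distance at which they were joined.
#' UPGMA guarantees this matrix is ultrametric.
#'
#' @param x An [UpgmaTree-class].
#' @return Symmetric labelled matrix.
#' @export
copheneticMatrix <- function(x) {
  n <- length(x@labels)
  sets <- .mergeLeafSets(x@merge)
  coph <- matrix(0, n, n, dimnames = list(x@labels, x@labels))
  for (m in seq_len(nrow(x@merge))) {
    kids <- x@merge[m, ]
    left <- if (kids[1L] < 0L) -kids[1L] else sets[[kids[1L]]]
    right <- if (kids[2L] < 0L) -kids[2L] else sets[[kids[2L]]]
    coph[left, right] <- 2 * x@height[m]
    coph[right, left] <- 2 * x@height[m]
  }
  coph
}

#' Serialize a UPGMA tree as Newick
#'
#' Branch lengths are height differences between parent and child (leaves
#' sit at height 0). Child order follows the deterministic founding-index
#' order of the tree. Labels containing Newick metacharacters are quoted
#' with single quotes (doubled inside).
#'
#' @param x An [UpgmaTree-class].
#' @param path Optional file path; when given the string is also written out.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when `path` is given.
#' @export
writeNewick <- function(x, path = NULL, digits = 10) {
  fmt <- function(v) sprintf("%.*g", digits, v)
  quoteLabel <- function(lab) {
    if (grepl("[][ ():;,']", lab)) {
      paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
    } else {
      lab
    }
  }
  nodeStr <- function(id) {
    if (id < 0L) {
      list(str = quoteLabel(x@labels[-id]), h = 0)
    } else {
      l <- nodeStr(x@merge[id, 1L])
      r <- nodeStr(x@merge[id, 2L])
      h <- x@height[id]
      list(str = paste0("(", l$str, ":", fmt(h - l$h), ",",
                        r$str, ":", fmt(h - r$h), ")"),
           h = h)
    }
  }
  nwk <- paste0(nodeStr(nrow(x@merge))$str, ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
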