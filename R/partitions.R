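# Subgroup partitions at every merge level of the tree.

#' Extract the subgroup partition at every tree level
#'
#' Level k is the partition into k subgroups obtained by undoing the last
#' k-1 merges of the tree (equivalently, cutting the dendrogram between
#' consecutive merge heights). Level 1 is the whole family, level N the
#' singleton partition, and each level refines the previous one. Subgroup
#' indices are canonical (numbered by first appearance in sequence order),
#' so permuting the input records permutes labels but not the partitions.
#'
#' @param x An [UpgmaTree-class].
#' @return A [PartitionSet-class].
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' partitionAt(treeLevels(upgmaTree(d)), 2)  # A,B together; C alone
#' @export
treeLevels <- function(x) {
  n <- length(x@labels)
  sets <- .mergeLeafSets(x@merge)
  canonical <- function(v) match(v, unique(v))
  lev <- matrix(0L, n, n, dimnames = list(NULL, x@labels))
  memb <- seq_len(n)
  lev[n, ] <- canonical(memb)
  for (m in seq_len(n - 1L)) {
    memb[sets[[m]]] <- n + m
    lev[n - m, ] <- canonical(memb)
  }
  new("PartitionSet", ids = x@labels, levels = lev)
}

#' @rdname PartitionSet-class
#' @export
setMethod("partitionAt", "PartitionSet", function(x, k) {
  n <- length(x@ids)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n) {
    .teaoStop("teao_bounds_error", sprintf("level must lie in 1..%d", n))
  }
  out <- x@levels[k, ]
  names(out) <- x@ids
  out
})

#' @rdname PartitionSet-class
#' @export
setMethod("nSequences", "PartitionSet", function(x) length(x@ids))

#' @rdname PartitionSet-class
#' @export
setMethod("seqIds", "PartitionSet", function(x) x@ids)

setMethod("show", "PartitionSet", function(object) {
  cat(sprintf("PartitionSet: %d levels over %d sequences\n",
              nrow(object@levels), length(object@ids)))
})
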