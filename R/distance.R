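# Pairwise p-distances feeding UPGMA.

#' Pairwise p-distance matrix
#'
#' For each pair of sequences, the fraction of mismatching columns among the
#' columns where both sequences carry a standard residue (gaps and ambiguity
#' codes are excluded pairwise). Pairs with no comparable column get
#' distance 1 with a warning, so sparse alignments degrade gracefully
#' instead of failing.
#'
#' @param x A [ProteinMSA-class].
#' @return A symmetric numeric matrix in [0, 1] with zero diagonal, labelled
#'   by sequence identifier.
#' @examples
#' msa <- ProteinMSA(c(a = "AAAA", b = "AAAC"))
#' pairwiseDistance(msa)["a", "b"]  # 0.25
#' @export
pairwiseDistance <- function(x) {
  codes <- .codeMatrix(x)
  std <- codes >= 1L & codes <= 20L
  storage.mode(std) <- "double"
  comparable <- tcrossprod(std)
  matches <- matrix(0, nrow(codes), nrow(codes))
  for (a in seq_len(20L)) {
    ind <- codes == a
    if (any(ind)) {
      storage.mode(ind) <- "double"
      matches <- matches + tcrossprod(ind)
    }
  }
  d <- 1 - matches / comparable
  noOverlap <- comparable == 0
  if (any(noOverlap[upper.tri(noOverlap)])) {
    warning(sum(noOverlap[upper.tri(noOverlap)]),
            " sequence pair(s) share no comparable column; distance set to 1")
    d[noOverlap] <- 1
  }
  diag(d) <- 0
  dimnames(d) <- list(seqIds(x), seqIds(x))
  d
}

#' Write a distance matrix as TSV
#'
#' Labels appear as header row and first column.
#'
#' @param d Symmetric labelled distance matrix (from [pairwiseDistance()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeDistanceMatrix <- function(d, path) {
  df <- data.frame(id = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTsv(df, path)
}

# shared validation for distance matrices entering UPGMA
.checkDistanceMatrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    .teaoStop("teao_matrix_error", "distance matrix must be square")
  }
  if (nrow(d) < 2L) {
    .teaoStop("teao_size_error", "need at least two taxa to cluster")
  }
  if (anyNA(d) || any(!is.finite(d))) {
    .teaoStop("teao_matrix_error", "distance matrix contains NA/NaN/Inf")
  }
  if (any(d < 0)) {
    .teaoStop("teao_matrix_error", "distance matrix contains negative entries")
  }
  if (max(abs(d - t(d))) > 1e-8) {
    .teaoStop("teao_matrix_error", "distance matrix must be symmetric")
  }
  if (any(diag(d) != 0)) {
    .teaoStop("teao_matrix_error", "distance matrix diagonal must be zero")
  }
  invisible(TRUE)
}
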