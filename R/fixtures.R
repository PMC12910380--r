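# fixtures: deterministic synthetic alignments with planted column classes.
#
# Emulates the classic synthetic-family validation design: sequences fall
# into subfamilies; columns are either conserved everywhere, conserved
# within each subfamily on subfamily-specific residues, i.i.d. random, or
# gap-riddled; optional uniform substitution noise on top. The planted
# ground truth makes parameter-recovery tests possible without any external
# data.

#' Generate a synthetic alignment with planted column classes
#'
#' Column classes (before noise):
#' \describe{
#'   \item{conserved}{one residue, drawn per column, in every sequence.}
#'   \item{subfamily_specific}{a distinct residue per subfamily, drawn
#'     without replacement so the column discriminates subfamilies
#'     maximally.}
#'   \item{random}{i.i.d. uniform over the 20 standard residues.}
#'   \item{gappy}{random residues, each cell replaced by a gap with
#'     probability `gapProbability`.}
#' }
#' Substitution noise then replaces each non-gap cell, with probability
#' `substitutionNoise`, by a residue drawn uniformly from the 19 others.
#' All randomness comes from a private generator seeded with `seed`; the
#' same spec yields byte-identical output and the global RNG state is left
#' untouched.
#'
#' @param nSubfamilies Number of subfamilies (2..20; default 4).
#' @param sequencesPerSubfamily Sequences per subfamily (default 8).
#' @param nColumns Alignment length (default 100).
#' @param columnClasses Character vector of length `nColumns` over the four
#'   class labels. Default: 10\% conserved, 10\% subfamily_specific, the
#'   rest random, in that order.
#' @param substitutionNoise Per-cell substitution probability (default 0).
#' @param gapProbability Gap probability inside gappy columns (default 0.3).
#' @param seed Integer seed (default 1).
#' @return A list with elements `msa` (a [ProteinMSA-class] with ids
#'   `SF<i>_S<j>`), `truth` (data.frame: column, class, planted residues)
#'   and `subfamilies` (named integer vector of planted subfamily labels).
#' @examples
#' fx <- simulateMsa(nSubfamilies = 3, sequencesPerSubfamily = 4,
#'                   nColumns = 20, seed = 7)
#' table(fx$truth$class)
#' @export
simulateMsa <- function(nSubfamilies = 4L, sequencesPerSubfamily = 8L,
                        nColumns = 100L, columnClasses = NULL,
                        substitutionNoise = 0, gapProbability = 0.3,
                        seed = 1L) {
  nSubfamilies <- as.integer(nSubfamilies)
  sequencesPerSubfamily <- as.integer(sequencesPerSubfamily)
  nColumns <- as.integer(nColumns)
  N <- nSubfamilies * sequencesPerSubfamily
  if (is.na(N) || N < 2L) {
    .teaoStop("teao_size_error",
              "need at least two sequences in total (subfamilies x size)")
  }
  if (nSubfamilies < 1L || nSubfamilies > 20L) {
    .teaoStop("teao_config_error",
              "nSubfamilies must lie in 1..20 (distinct planted residues)")
  }
  if (nColumns < 1L) {
    .teaoStop("teao_config_error", "nColumns must be positive")
  }
  classes <- c("conserved", "subfamily_specific", "random", "gappy")
  if (is.null(columnClasses)) {
    nCons <- max(1L, round(0.1 * nColumns))
    nSpec <- max(1L, round(0.1 * nColumns))
    if (nCons + nSpec > nColumns) {
      nCons <- nColumns %/% 2L
      nSpec <- nColumns - nCons
    }
    columnClasses <- c(rep("conserved", nCons), rep("subfamily_specific", nSpec),
                      rep("random", nColumns - nCons - nSpec))
  }
  if (length(columnClasses) != nColumns ||
      !all(columnClasses %in% classes)) {
    .teaoStop("teao_config_error", paste0(
      "columnClasses must be length nColumns over {",
      paste(classes, collapse = ", "), "}"))
  }
  if (substitutionNoise < 0 || substitutionNoise > 1 ||
      gapProbability < 0 || gapProbability > 1) {
    .teaoStop("teao_config_error", "probabilities must lie in [0, 1]")
  }

  subfam <- rep(seq_len(nSubfamilies), each = sequencesPerSubfamily)
  .withSeed(seed, {
    m <- matrix(.GAP, nrow = N, ncol = nColumns)
    planted <- character(nColumns)
    for (c in seq_len(nColumns)) {
      cls <- columnClasses[c]
      if (cls == "conserved") {
        r <- sample(.AA20, 1L)
        m[, c] <- r
        planted[c] <- r
      } else if (cls == "subfamily_specific") {
        rs <- sample(.AA20, nSubfamilies, replace = FALSE)
        m[, c] <- rs[subfam]
        planted[c] <- paste(rs, collapse = ",")
      } else if (cls == "random") {
        m[, c] <- sample(.AA20, N, replace = TRUE)
        planted[c] <- ""
      } else {                         # gappy
        m[, c] <- sample(.AA20, N, replace = TRUE)
        gapped <- stats::runif(N) < gapProbability
        m[gapped, c] <- .GAP
        planted[c] <- ""
      }
    }
    if (substitutionNoise > 0) {
      u <- matrix(stats::runif(N * nColumns), N, nColumns)
      hit <- which(u < substitutionNoise & m != .GAP)
      if (length(hit)) {
        # draw uniformly among the 19 residues other than the current one
        shift <- sample.int(19L, length(hit), replace = TRUE)
        cur <- match(m[hit], .AA20)
        m[hit] <- .AA20[((cur - 1L + shift) %% 20L) + 1L]
      }
    }
    ids <- sprintf("SF%d_S%d", subfam,
                   stats::ave(subfam, subfam, FUN = seq_along))
    seqs <- apply(m, 1L, paste, collapse = "")
    names(seqs) <- ids
    names(subfam) <- ids
    list(msa = ProteinMSA(seqs),
         truth = data.frame(column = seq_len(nColumns),
                            class = columnClasses,
                            planted = planted,
                            stringsAsFactors = FALSE),
         subfamilies = subfam)
  })
}

#' Write a simulated alignment and its ground truth
#'
#' @param fixture The list returned by [simulateMsa()].
#' @param fastaPath Output FASTA path.
#' @param truthPath Output ground-truth TSV path.
#' @return Invisibly, the two paths.
#' @export
writeFixture <- function(fixture, fastaPath, truthPath) {
  writeMsa(fixture$msa, fastaPath)
  .writeTsv(fixture$truth, truthPath)
  invisible(c(fastaPath, truthPath))
}
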