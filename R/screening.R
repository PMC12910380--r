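# screening: rule-based nomination of candidate specificity/rheostat
# positions. Criteria follow the field's screening practice: high entropy,
# a minimum number of distinct substitutions, away from the termini, and
# not on a user-supplied exclusion list (catalytic/substrate-binding sites
# are domain knowledge, not computed).

#' Read an exclusion list of reference residue numbers
#'
#' Plain text, one entry per line: a single number or a closed range
#' `a-b`. Blank lines and `#` comments are ignored.
#'
#' @param path Path to the exclusion file.
#' @return Sorted integer vector of residue numbers.
#' @export
readExclusionList <- function(path) {
  if (!file.exists(path)) {
    .teaoStop("teao_io_error", paste0("exclusion file not found: ", path))
  }
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- integer(0L)
  for (ln in lines) {
    if (grepl("^\\d+-\\d+$", ln)) {
      ab <- as.integer(strsplit(ln, "-", fixed = TRUE)[[1L]])
      out <- c(out, seq(ab[1L], ab[2L]))
    } else if (grepl("^\\d+$", ln)) {
      out <- c(out, as.integer(ln))
    } else {
      .teaoStop("teao_format_error", paste0(
        "cannot parse exclusion entry: '", ln, "'"))
    }
  }
  sort(unique(out))
}

#' Screen alignment positions for candidate rheostat/specificity residues
#'
#' Evaluates every reference-mapped column against four criteria and
#' returns the full audit table (failing rows are retained with their
#' failure reasons):
#' \describe{
#'   \item{distinct}{at least `minDistinct` distinct standard residues
#'     observed (default 10).}
#'   \item{entropy}{the chosen metric (`h_global` or `specificity`) at or
#'     above the threshold. When `entropyThreshold` is `NULL` the threshold
#'     is the `entropyQuantile` quantile (default: top quartile) of the
#'     metric over reference-mapped columns -- scale-free since no absolute
#'     cutoff is canonical.}
#'   \item{terminal}{reference position more than `terminalExclusion`
#'     residues away from either end of the reference sequence.}
#'   \item{excluded}{reference position not on `exclusionPositions`.}
#' }
#'
#' @param entropy An [EntropyProfile-class].
#' @param map A [PositionMap-class] on the same alignment.
#' @param msa The [ProteinMSA-class] the profiles were computed from
#'   (residue frequencies per candidate are reported).
#' @param properties Optional [PropertyProfile-class]; per-descriptor
#'   standard deviations are appended.
#' @param minDistinct Minimum distinct residues (1..20, default 10).
#' @param entropyMetric `"global"` (default) or `"specificity"`.
#' @param entropyThreshold Absolute threshold in metric units, or `NULL`.
#' @param entropyQuantile Quantile used when `entropyThreshold` is `NULL`.
#' @param terminalExclusion Reference residues trimmed from each end
#'   (default 10).
#' @param exclusionPositions Integer vector of reference residue numbers to
#'   exclude (see [readExclusionList()]).
#' @return A data.frame sorted by the metric (descending, ties by reference
#'   position), with per-criterion pass flags, an overall `pass`, and
#'   `fail_reasons`; the applied configuration is in `attr(, "config")`.
#' @export
screenPositions <- function(entropy, map, msa, properties = NULL,
                            minDistinct = 10L,
                            entropyMetric = c("global", "specificity"),
                            entropyThreshold = NULL,
                            entropyQuantile = 0.75,
                            terminalExclusion = 10L,
                            exclusionPositions = integer(0L)) {
  entropyMetric <- match.arg(entropyMetric)
  minDistinct <- as.integer(minDistinct)
  terminalExclusion <- as.integer(terminalExclusion)
  if (minDistinct < 1L || minDistinct > 20L) {
    .teaoStop("teao_config_error", "minDistinct must lie in 1..20")
  }
  if (terminalExclusion < 0L) {
    .teaoStop("teao_config_error", "terminalExclusion must be >= 0")
  }
  refLen <- length(residueToColumn(map))
  exclusionPositions <- as.integer(exclusionPositions)
  if (length(exclusionPositions) &&
      (min(exclusionPositions) < 1L || max(exclusionPositions) > refLen)) {
    .teaoStop("teao_bounds_error", sprintf(
      "exclusion positions must lie in 1..%d (reference length)", refLen))
  }

  cols <- residueToColumn(map)
  refPos <- seq_len(refLen)
  metric <- switch(entropyMetric,
                   global = hGlobal(entropy)[cols],
                   specificity = specificity(entropy)[cols])
  if (is.null(entropyThreshold)) {
    entropyThreshold <- unname(quantile(metric, entropyQuantile, type = 7))
  }

  codes <- .codeMatrix(msa)
  residueStr <- vapply(cols, function(cc) {
    v <- codes[, cc]
    counts <- tabulate(v[v >= 1L & v <= 20L], nbins = 20L)
    obs <- which(counts > 0L)
    obs <- obs[order(-counts[obs], .AA20[obs])]
    paste(sprintf("%s:%d", .AA20[obs], counts[obs]), collapse = ",")
  }, "")

  passDistinct <- nDistinct(entropy)[cols] >= minDistinct
  passEntropy <- metric >= entropyThreshold
  passTerminal <- refPos > terminalExclusion &
    refPos <= refLen - terminalExclusion
  passExcluded <- !(refPos %in% exclusionPositions)
  pass <- passDistinct & passEntropy & passTerminal & passExcluded

  reasons <- vapply(seq_along(refPos), function(i) {
    r <- c(if (!passDistinct[i]) "distinct",
           if (!passEntropy[i]) "entropy",
           if (!passTerminal[i]) "terminal",
           if (!passExcluded[i]) "excluded")
    paste(r, collapse = ",")
  }, "")

  df <- data.frame(
    ref_residue = refPos,
    column = cols,
    h_global = hGlobal(entropy)[cols],
    h_avg = hAverage(entropy)[cols],
    specificity = specificity(entropy)[cols],
    n_distinct = nDistinct(entropy)[cols],
    residues = residueStr,
    stringsAsFactors = FALSE)
  if (!is.null(properties)) {
    sd <- sdMatrix(properties)[cols, , drop = FALSE]
    colnames(sd) <- paste0(descriptorNames(properties), "_sd")
    df <- cbind(df, as.data.frame(sd, row.names = NULL))
  }
  df$pass_distinct <- passDistinct
  df$pass_entropy <- passEntropy
  df$pass_terminal <- passTerminal
  df$pass_excluded <- passExcluded
  df$pass <- pass
  df$fail_reasons <- reasons

  ord <- order(-df[[switch(entropyMetric, global = "h_global",
                           specificity = "specificity")]], df$ref_residue)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "config") <- list(
    min_distinct = minDistinct, entropy_metric = entropyMetric,
    entropy_threshold = entropyThreshold,
    terminal_exclusion = terminalExclusion,
    exclusion_positions = exclusionPositions)
  df
}
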