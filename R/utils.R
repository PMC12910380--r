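# Alphabet bookkeeping shared by all modules.
#
# Integer codes: 1..20 the standard residues (alphabetical), 0 the gap,
# 21 ambiguity codes (X/B/Z/J/U/O). Ambiguity letters have no single identity
# and no descriptor values, so they never enter residue counts, entropy
# distributions or property profiles.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AMBIG <- c("X", "B", "Z", "J", "U", "O")
.GAP <- "-"
.AMBIG_CODE <- 21L

#' Maximum per-column entropy in bits
#'
#' `log2(20)`, the entropy of a column uniform over the 20 standard amino
#' acids; used to normalize conservation and specificity scores.
#' @return A single number (about 4.3219).
#' @export
maxEntropyBits <- function() log2(20)

# character vector -> integer codes (NA for letters outside the alphabet)
.encodeResidues <- function(chars) {
  code <- match(chars, .AA20)
  code[chars == .GAP] <- 0L
  code[chars %in% .AMBIG] <- .AMBIG_CODE
  code
}

# structured conditions so callers (and the CLI) can dispatch on error class
.teaoStop <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "teao_error")))
}

# Evaluate `expr` with a private RNG stream seeded from `seed`; the global
# .Random.seed is restored afterwards so library code never perturbs user
# randomness.
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    .teaoStop("teao_config_error", "seed must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(expr)
}

# population entropy (bits) of one count vector over standard residues
.entropyOfCounts <- function(counts) {
  tot <- sum(counts)
  if (tot <= 1) {
    return(0)
  }
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

# 20 x L (or 21 x L with the gap row when gapAsSymbol) count matrix -> H per column
.entropyColumns <- function(cnt) {
  tot <- colSums(cnt)
  denom <- pmax(tot, 1)
  p <- sweep(cnt, 2L, denom, "/")
  plogp <- p * log2(p)
  plogp[!is.finite(plogp)] <- 0
  h <- -colSums(plogp)
  h[tot <= 1] <- 0
  h[h == 0] <- 0  # normalize IEEE negative zero
  h
}

.fmtNum <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

# deterministic TSV writer used for all tabular outputs
.writeTsv <- function(df, path) {
  write.table(df, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}
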