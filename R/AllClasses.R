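#' ProteinMSA: a validated protein multiple sequence alignment
#'
#' Wraps a [Biostrings::AAStringSet] of equal-width, gapped protein
#' sequences. Validity enforces the alignment contract used throughout the
#' package: at least two records, identical lengths, unique identifiers
#' (FASTA header up to the first whitespace), and an alphabet restricted to
#' the 20 standard residues, the gap character `-` and the ambiguity codes
#' X/B/Z/J/U/O. Sequences are upper-cased and `.` is normalized to `-` on
#' construction.
#'
#' @slot seqs An `AAStringSet`, names are the identifiers.
#' @slot descriptions Full FASTA headers, parallel to `seqs`.
#' @export
setClass("ProteinMSA",
  representation(seqs = "AAStringSet", descriptions = "character"),
  validity = function(object) {
    n <- length(object@seqs)
    if (n < 2L) {
      return("an alignment needs at least two sequences")
    }
    w <- Biostrings::width(object@seqs)
    if (length(unique(w)) != 1L) {
      return("all sequences must have identical length")
    }
    if (w[1L] < 1L) {
      return("alignment must have at least one column")
    }
    ids <- names(object@seqs)
    if (is.null(ids) || anyNA(ids) || any(ids == "")) {
      return("all sequences must be named")
    }
    if (anyDuplicated(ids)) {
      return("sequence identifiers must be unique")
    }
    if (length(object@descriptions) != n) {
      return("descriptions must parallel the sequences")
    }
    letters <- Biostrings::uniqueLetters(object@seqs)
    bad <- setdiff(letters, c(.AA20, .AMBIG, .GAP))
    if (length(bad)) {
      return(paste0("illegal alignment letters: ", paste(bad, collapse = " ")))
    }
    TRUE
  }
)

#' PositionMap: alignment columns vs reference residue numbering
#'
#' Maps 1-based alignment columns to 1-based residue numbers in the ungapped
#' reference sequence and back. Columns where the reference carries a gap
#' have no residue number.
#'
#' @slot referenceId Identifier of the reference sequence.
#' @slot columnToResidue Integer per column; `NA` where the reference is gapped.
#' @slot residueToColumn Strictly increasing column index per reference residue.
#' @export
setClass("PositionMap",
  representation(referenceId = "character",
                 columnToResidue = "integer",
                 residueToColumn = "integer"),
  validity = function(object) {
    r2c <- object@residueToColumn
    if (length(r2c) > 1L && any(diff(r2c) <= 0L)) {
      return("residueToColumn must be strictly increasing")
    }
    mapped <- which(!is.na(object@columnToResidue))
    if (!identical(as.integer(r2c), as.integer(mapped))) {
      return("columnToResidue and residueToColumn are inconsistent")
    }
    if (length(r2c) &&
        !identical(object@columnToResidue[r2c], seq_along(r2c))) {
      return("residue -> column -> residue round trip is not the identity")
    }
    TRUE
  }
)

#' ResidueCounts: composition of one alignment column
#'
#' Counts of the 20 standard residues in a column; gaps and ambiguity codes
#' are tallied separately and never inside `counts`.
#'
#' @slot columnIndex 1-based column index.
#' @slot counts Named integer vector over the 20 standard residues.
#' @slot nGap Number of gap characters.
#' @slot nAmbiguous Number of ambiguity codes (X/B/Z/J/U/O).
#' @export
setClass("ResidueCounts",
  representation(columnIndex = "integer", counts = "integer",
                 nGap = "integer", nAmbiguous = "integer"),
  validity = function(object) {
    if (!identical(names(object@counts), .AA20)) {
      return("counts must cover exactly the 20 standard residues")
    }
    if (any(object@counts < 0L) || object@nGap < 0L || object@nAmbiguous < 0L) {
      return("counts must be non-negative")
    }
    TRUE
  }
)

#' UpgmaTree: a deterministic UPGMA dendrogram
#'
#' Binary merge tree in `hclust` convention: row m of `merge` lists the two
#' children of the m-th merge (negative = leaf index, positive = earlier
#' merge row); `height[m]` is half the between-cluster average distance at
#' that merge, so cophenetic distances equal the merging average distances.
#' Children are ordered by founding index (the smallest original leaf index
#' in the cluster), which makes the tree bit-reproducible.
#'
#' @slot labels Leaf labels in input order.
#' @slot merge Integer matrix (N-1) x 2 in `hclust` convention.
#' @slot height Merge heights (half average distances), non-decreasing.
#' @slot order Leaf ordering for plotting (left-to-right recursion).
#' @export
setClass("UpgmaTree",
  representation(labels = "character", merge = "matrix",
                 height = "numeric", order = "integer"),
  validity = function(object) {
    n <- length(object@labels)
    if (nrow(object@merge) != n - 1L || ncol(object@merge) != 2L) {
      return("merge must be an (N-1) x 2 matrix")
    }
    if (length(object@height) != n - 1L) {
      return("one height per merge required")
    }
    if (length(object@height) > 1L &&
        any(diff(object@height) < -1e-9 * max(object@height))) {
      return("merge heights must be non-decreasing (UPGMA monotonicity)")
    }
    if (anyNA(object@height) || any(object@height < 0)) {
      return("heights must be non-negative and finite")
    }
    TRUE
  }
)

#' PartitionSet: subgroup assignments at every tree level
#'
#' For each level k in 1..N, the assignment of every sequence to one of k
#' subgroups, obtained by undoing the last k-1 merges of an [UpgmaTree].
#' Subgroup indices are canonical: numbered by first appearance in sequence
#' order, so partitions are comparable across runs.
#'
#' @slot ids Sequence identifiers (column order of `levels`).
#' @slot levels Integer matrix, row k = partition with k subgroups.
#' @export
setClass("PartitionSet",
  representation(ids = "character", levels = "matrix"),
  validity = function(object) {
    n <- length(object@ids)
    if (!identical(dim(object@levels), c(n, n))) {
      return("levels must be an N x N matrix (level k in row k)")
    }
    for (k in seq_len(n)) {
      if (length(unique(object@levels[k, ])) != k) {
        return(sprintf("level %d must have exactly %d subgroups", k, k))
      }
    }
    if (any(object@levels[1L, ] != 1L)) {
      return("level 1 must place all sequences in one subgroup")
    }
    TRUE
  }
)

#' EntropyProfile: per-column entropy, conservation and specificity
#'
#' The result of [teaoProfile()]. `hLevel` holds the size-weighted
#' within-subgroup entropy for every tree level (row k) and column; `hAvg`
#' is the unweighted mean of the rows selected by `levelsUsed`;
#' `conservation = 1 - hGlobal/normalizer` and
#' `specificity = (hGlobal - hAvg)/normalizer` with
#' `normalizer = log2(alphabet size)`.
#'
#' @slot hGlobal Per-column global Shannon entropy (bits).
#' @slot hLevel Level x column matrix of subgroup-averaged entropies (bits).
#' @slot hAvg Per-column entropy averaged across `levelsUsed` (bits).
#' @slot conservation Per-column score in [0, 1].
#' @slot specificity Per-column score in [0, 1].
#' @slot gapFraction Per-column fraction of gap characters.
#' @slot nDistinct Per-column number of distinct standard residues.
#' @slot lowSupport Per-column flag: fewer than 2 counted residues.
#' @slot levelsUsed Which partition levels entered `hAvg`.
#' @slot normalizer Entropy normalizer in bits (log2 of alphabet size).
#' @export
setClass("EntropyProfile",
  representation(hGlobal = "numeric", hLevel = "matrix", hAvg = "numeric",
                 conservation = "numeric", specificity = "numeric",
                 gapFraction = "numeric", nDistinct = "integer",
                 lowSupport = "logical", levelsUsed = "integer",
                 normalizer = "numeric"),
  validity = function(object) {
    L <- length(object@hGlobal)
    lens <- c(length(object@hAvg), length(object@conservation),
              length(object@specificity), length(object@gapFraction),
              length(object@nDistinct), length(object@lowSupport),
              ncol(object@hLevel))
    if (any(lens != L)) {
      return("all per-column slots must have the same length")
    }
    if (any(object@hGlobal < -1e-9) ||
        any(object@hGlobal > object@normalizer + 1e-9)) {
      return("global entropy must lie in [0, log2(alphabet)]")
    }
    if (any(object@conservation < -1e-9 | object@conservation > 1 + 1e-9) ||
        any(object@specificity < -1e-9 | object@specificity > 1 + 1e-9)) {
      return("conservation and specificity must lie in [0, 1]")
    }
    TRUE
  }
)

#' PropertyTable: per-residue physicochemical descriptors
#'
#' A named set of D numeric descriptors covering exactly the 20 standard
#' amino acids (no gap or ambiguity entries). The built-in instance is the
#' three-component z-scale set (lipophilicity, steric bulk/polarizability,
#' polarity/charge); see [builtinZscales()].
#'
#' @slot name Table name (stamped into outputs).
#' @slot values 20 x D numeric matrix, rownames the residues.
#' @slot descriptorNames Column labels.
#' @slot descriptorLabels Human-readable descriptor descriptions.
#' @export
setClass("PropertyTable",
  representation(name = "character", values = "matrix",
                 descriptorNames = "character",
                 descriptorLabels = "character"),
  validity = function(object) {
    v <- object@values
    if (!identical(sort(rownames(v)), .AA20)) {
      return("values must cover exactly the 20 standard amino acids")
    }
    if (ncol(v) < 1L) {
      return("at least one descriptor required")
    }
    if (!all(is.finite(v))) {
      return("all descriptor values must be finite")
    }
    if (length(object@descriptorNames) != ncol(v)) {
      return("one descriptor name per column required")
    }
    TRUE
  }
)

#' PropertyProfile: per-column descriptor standard deviations
#'
#' Population standard deviation of each descriptor over the residue
#' occurrences in each column (gaps/ambiguity excluded). Columns with fewer
#' than two scored residues are flagged and carry 0 by convention.
#'
#' @slot sd Column x descriptor matrix of standard deviations (>= 0).
#' @slot descriptorNames Descriptor labels (column names of `sd`).
#' @slot lowSupport Per-column flag: fewer than 2 scored residues.
#' @slot tableName Name of the [PropertyTable] used.
#' @export
setClass("PropertyProfile",
  representation(sd = "matrix", descriptorNames = "character",
                 lowSupport = "logical", tableName = "character"),
  validity = function(object) {
    if (nrow(object@sd) != length(object@lowSupport)) {
      return("one low-support flag per column required")
    }
    if (any(object@sd < 0)) {
      return("standard deviations must be non-negative")
    }
    if (any(object@sd[object@lowSupport, ] != 0)) {
      return("low-support columns must carry sd 0")
    }
    TRUE
  }
)

#' TaxonomyStore: local NCBI-style taxonomy tables
#'
#' Parsed accession-to-taxid mapping plus the parent/rank/name tables needed
#' to reconstruct lineages offline. Lineage walks are cycle-guarded and must
#' terminate at the root (the taxid whose parent is itself).
#'
#' @slot accessionToTaxid Named integer vector (names = accessions).
#' @slot parent Named integer vector (names = taxids).
#' @slot rank Named character vector (names = taxids).
#' @slot sciName Named character vector (names = taxids).
#' @slot rootTaxid The root taxid.
#' @export
setClass("TaxonomyStore",
  representation(accessionToTaxid = "integer", parent = "integer",
                 rank = "character", sciName = "character",
                 rootTaxid = "integer"))

#' LineageAnnotation: taxonomic lineages for alignment sequences
#'
#' Every alignment identifier is either mapped (taxid plus root-to-leaf
#' lineage) or listed in `unmapped`; nothing is dropped silently.
#'
#' @slot ids Alignment identifiers, in alignment order.
#' @slot taxid Named integer per identifier (`NA` when unmapped).
#' @slot lineages Named list; per mapped identifier a data.frame with
#'   columns taxid, rank, name ordered root to leaf.
#' @slot unmapped Identifiers without a taxonomy assignment.
#' @export
setClass("LineageAnnotation",
  representation(ids = "character", taxid = "integer",
                 lineages = "list", unmapped = "character"),
  validity = function(object) {
    mapped <- object@ids[!is.na(object@taxid)]
    if (!setequal(c(mapped, object@unmapped), object@ids) ||
        length(mapped) + length(object@unmapped) != length(object@ids)) {
      return("mapped + unmapped must partition the identifiers")
    }
    TRUE
  }
)
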