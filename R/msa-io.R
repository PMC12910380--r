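# msa_io: reading, validating and indexing aligned FASTA.

#' Construct a ProteinMSA from sequences
#'
#' Normalizes (upper case, `.` -> `-`) and validates a set of aligned protein
#' sequences. Errors are structured conditions: ragged lengths signal
#' `teao_shape_error` naming the offending record, fewer than two records
#' signal `teao_size_error`, letters outside the alphabet signal
#' `teao_character_error` with record, column and character, duplicate
#' identifiers signal `teao_id_error`.
#'
#' @param x Named character vector of aligned sequences, or an
#'   `AAStringSet`.
#' @param descriptions Optional full headers (defaults to the names).
#' @return A [ProteinMSA-class] object.
#' @examples
#' msa <- ProteinMSA(c(s1 = "MK-LV", s2 = "MKALV"))
#' nColumns(msa)
#' @export
ProteinMSA <- function(x, descriptions = NULL) {
  if (is(x, "XStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x)) {
    .teaoStop("teao_format_error", "sequences must be a named character vector")
  }
  ids <- names(x)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    .teaoStop("teao_id_error", "every sequence needs a non-empty identifier")
  }
  if (length(x) < 2L) {
    .teaoStop("teao_size_error", sprintf(
      "an alignment needs at least two sequences (got %d)", length(x)))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    .teaoStop("teao_id_error", paste0(
      "duplicate sequence identifiers: ", paste(unique(dup), collapse = ", ")))
  }
  seqs <- chartr(".", .GAP, toupper(x))
  len <- nchar(seqs)
  if (length(unique(len)) != 1L) {
    off <- which(len != len[1L])[1L]
    .teaoStop("teao_shape_error", sprintf(
      "ragged alignment: record '%s' has length %d but '%s' has length %d",
      ids[off], len[off], ids[1L], len[1L]))
  }
  allowed <- c(.AA20, .AMBIG, .GAP)
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    bad <- which(!(chars %in% allowed))
    if (length(bad)) {
      .teaoStop("teao_character_error", sprintf(
        "illegal character '%s' in record '%s' at column %d",
        chars[bad[1L]], ids[i], bad[1L]))
    }
  }
  if (is.null(descriptions)) {
    descriptions <- ids
  }
  new("ProteinMSA", seqs = Biostrings::AAStringSet(seqs),
      descriptions = unname(descriptions))
}

#' Read an aligned FASTA file
#'
#' Identifiers are the FASTA header up to the first whitespace; the full
#' header is retained as the description. Record order is preserved.
#'
#' @param path Path to an aligned FASTA file.
#' @return A [ProteinMSA-class] object.
#' @seealso [writeMsa()]
#' @export
readMsa <- function(path) {
  if (!file.exists(path)) {
    .teaoStop("teao_io_error", paste0("input file not found: ", path))
  }
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    .teaoStop("teao_io_error",
                              paste0("cannot parse FASTA: ", conditionMessage(e)))
                  })
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  x <- as.character(raw)
  names(x) <- ids
  ProteinMSA(x, descriptions = headers)
}

#' Write an alignment as FASTA
#'
#' 60 characters per line; headers are the stored descriptions, so a
#' read/write round trip is lossless.
#'
#' @param x A [ProteinMSA-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeMsa <- function(x, path) {
  out <- x@seqs
  names(out) <- ifelse(x@descriptions == seqIds(x) |
                         startsWith(x@descriptions, paste0(seqIds(x), " ")),
                       x@descriptions,
                       seqIds(x))
  Biostrings::writeXStringSet(out, filepath = path, width = 60L)
  invisible(path)
}

#' @rdname ProteinMSA-class
#' @export
setMethod("nSequences", "ProteinMSA", function(x) length(x@seqs))

#' @rdname ProteinMSA-class
#' @export
setMethod("nColumns", "ProteinMSA",
          function(x) unname(Biostrings::width(x@seqs)[1L]))

#' @rdname ProteinMSA-class
#' @export
setMethod("seqIds", "ProteinMSA", function(x) names(x@seqs))

#' @rdname ProteinMSA-class
#' @export
setMethod("seqDescriptions", "ProteinMSA", function(x) x@descriptions)

#' @rdname ProteinMSA-class
#' @export
setMethod("as.character", "ProteinMSA", function(x) as.character(x@seqs))

#' Subset an alignment by sequence
#' @param x A `ProteinMSA`.
#' @param i Index, logical or identifier vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "ProteinMSA", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    i <- match(i, seqIds(x))
  }
  new("ProteinMSA", seqs = x@seqs[i], descriptions = x@descriptions[i])
})

setMethod("show", "ProteinMSA", function(object) {
  cat(sprintf("ProteinMSA: %d sequences x %d columns\n",
              nSequences(object), nColumns(object)))
  ids <- seqIds(object)
  cat("  ids:", paste(head(ids, 5L), collapse = ", "),
      if (length(ids) > 5L) "..." else "", "\n")
})

# character matrix view (sequences x columns)
.alignMatrix <- function(x) {
  m <- as.matrix(x@seqs)
  rownames(m) <- seqIds(x)
  m
}

# integer code matrix (1..20 residues, 0 gap, 21 ambiguous)
.codeMatrix <- function(x) {
  m <- .alignMatrix(x)
  codes <- .encodeResidues(m)
  dim(codes) <- dim(m)
  dimnames(codes) <- dimnames(m)
  codes
}

# counts of the 20 residues (20 x L) plus gap/ambiguity tallies per column
.countsArray <- function(codes) {
  L <- ncol(codes)
  perResidue <- vapply(seq_len(20L),
                       function(a) colSums(codes == a),
                       numeric(L))
  cnt <- t(matrix(perResidue, nrow = L))  # robust to L == 1
  rownames(cnt) <- .AA20
  list(counts = cnt,
       gaps = colSums(codes == 0L),
       ambiguous = colSums(codes == .AMBIG_CODE))
}

#' Map alignment columns to reference residue numbers
#'
#' Builds the correspondence between 1-based alignment columns and 1-based
#' residue positions of the ungapped reference sequence. Columns where the
#' reference carries a gap are unmapped. If `referenceId` is omitted the
#' first record is used and a message is emitted.
#'
#' @param x A [ProteinMSA-class].
#' @param referenceId Identifier of the reference sequence, or `NULL`.
#' @return A [PositionMap-class].
#' @examples
#' msa <- ProteinMSA(c(ref = "AC-GT", other = "ACAGT"))
#' map <- mapReferencePositions(msa, "ref")
#' residueToColumn(map)  # 1 2 4 5
#' @export
mapReferencePositions <- function(x, referenceId = NULL) {
  ids <- seqIds(x)
  if (is.null(referenceId)) {
    referenceId <- ids[1L]
    message("no reference id given; using first record '", referenceId, "'")
  }
  if (!(referenceId %in% ids)) {
    .teaoStop("teao_lookup_error", paste0(
      "reference id '", referenceId, "' not in alignment; available: ",
      paste(head(ids, 20L), collapse = ", "),
      if (length(ids) > 20L) ", ..." else ""))
  }
  chars <- strsplit(as.character(x@seqs[[match(referenceId, ids)]]),
                    "", fixed = TRUE)[[1L]]
  isRes <- chars != .GAP
  columnToResidue <- rep(NA_integer_, length(chars))
  columnToResidue[isRes] <- seq_len(sum(isRes))
  if (!any(isRes)) {
    warning("reference sequence '", referenceId,
            "' is all gaps; position map is empty")
  }
  new("PositionMap", referenceId = referenceId,
      columnToResidue = columnToResidue,
      residueToColumn = which(isRes))
}

#' @rdname PositionMap-class
#' @param x A `PositionMap`.
#' @export
referenceId <- function(x) x@referenceId

#' @rdname PositionMap-class
#' @export
columnToResidue <- function(x) x@columnToResidue

#' @rdname PositionMap-class
#' @export
residueToColumn <- function(x) x@residueToColumn

setMethod("show", "PositionMap", function(object) {
  cat(sprintf("PositionMap: reference '%s', %d of %d columns mapped\n",
              object@referenceId, length(object@residueToColumn),
              length(object@columnToResidue)))
})

#' Residue composition of one alignment column
#'
#' @param x A [ProteinMSA-class].
#' @param column 1-based column index.
#' @return A [ResidueCounts-class]: counts over the 20 standard residues,
#'   with gaps and ambiguity codes tallied separately.
#' @examples
#' msa <- ProteinMSA(c(a = "AA", b = "A-", c = "AX"))
#' columnComposition(msa, 2)
#' @export
columnComposition <- function(x, column) {
  L <- nColumns(x)
  column <- as.integer(column)
  if (length(column) != 1L || is.na(column) || column < 1L || column > L) {
    .teaoStop("teao_bounds_error", sprintf(
      "column index must lie in 1..%d", L))
  }
  codes <- .codeMatrix(x)[, column]
  counts <- as.integer(tabulate(codes[codes >= 1L & codes <= 20L],
                                nbins = 20L))
  names(counts) <- .AA20
  new("ResidueCounts", columnIndex = column, counts = counts,
      nGap = sum(codes == 0L), nAmbiguous = sum(codes == .AMBIG_CODE))
}

#' @rdname ResidueCounts-class
#' @param x A `ResidueCounts`.
#' @export
residueCounts <- function(x) {
  out <- x@counts
  names(out) <- .AA20
  out
}

#' @rdname ResidueCounts-class
#' @export
nGaps <- function(x) x@nGap

#' @rdname ResidueCounts-class
#' @export
nAmbiguous <- function(x) x@nAmbiguous

setMethod("show", "ResidueCounts", function(object) {
  obs <- residueCounts(object)
  obs <- obs[obs > 0L]
  cat(sprintf("ResidueCounts (column %d): %s | gaps %d, ambiguous %d\n",
              object@columnIndex,
              paste(sprintf("%s:%d", names(obs), obs), collapse = " "),
              object@nGap, object@nAmbiguous))
})

#' Consensus sequence of an alignment
#'
#' Most frequent standard residue per column, ties broken alphabetically;
#' columns without any standard residue yield `-`.
#'
#' @param x A [ProteinMSA-class].
#' @return A single character string of length `nColumns(x)`.
#' @export
consensusSequence <- function(x) {
  cnt <- .countsArray(.codeMatrix(x))$counts
  picks <- apply(cnt, 2L, function(col) {
    if (max(col) == 0L) {
      return(.GAP)
    }
    .AA20[which.max(col)]  # which.max takes the first, i.e. alphabetical
  })
  paste(picks, collapse = "")
}
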