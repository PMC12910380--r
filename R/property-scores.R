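# property_scores: z-scale (and custom) per-column variability profiles.
#
# Entropy treats residues as opaque symbols; these profiles quantify how
# different the residues at a column actually are in physicochemical space.

.ZSCALE_LABELS <- c(z1 = "lipophilicity",
                    z2 = "steric bulk / polarizability",
                    z3 = "polarity / charge")

#' Built-in three-component z-scale descriptor table
#'
#' The first three z-scales of the extended z-scale amino-acid descriptor
#' set (principal components of a large panel of experimental
#' physicochemical measurements): z1 lipophilicity, z2 steric
#' bulk/polarizability, z3 polarity/charge. Scales 4-5 are deliberately
#' absent (low explained variance, 13% and 6%, and harder to interpret).
#' Shipped as a versioned TSV under `inst/extdata` with a provenance note.
#'
#' @return A [PropertyTable-class] with 20 rows and 3 descriptors.
#' @examples
#' propertyValues(builtinZscales())["W", ]
#' @export
builtinZscales <- function() {
  path <- system.file("extdata", "zscales3.tsv", package = "teao",
                      mustWork = TRUE)
  loadPropertyTable(path, name = "zscales3-sandberg1998")
}

#' Load a custom per-residue property table
#'
#' TSV or CSV with a header row: first column the residue one-letter code,
#' remaining columns numeric descriptors (any number >= 1). The table must
#' cover each of the 20 standard amino acids exactly once; `#` lines are
#' comments.
#'
#' @param path Path to the table.
#' @param name Table name stamped into outputs (default: file name).
#' @return A [PropertyTable-class].
#' @export
loadPropertyTable <- function(path, name = NULL) {
  if (!file.exists(path)) {
    .teaoStop("teao_io_error", paste0("property table not found: ", path))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    read.delim(path, sep = sep, header = TRUE, comment.char = "#",
               stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) .teaoStop("teao_schema_error", paste0(
      "cannot parse property table: ", conditionMessage(e))))
  if (ncol(df) < 2L) {
    .teaoStop("teao_schema_error",
              "property table needs a residue column plus >= 1 descriptor")
  }
  res <- toupper(trimws(as.character(df[[1L]])))
  dup <- unique(res[duplicated(res)])
  if (length(dup)) {
    .teaoStop("teao_schema_error", paste0(
      "duplicate residue rows: ", paste(dup, collapse = ", ")))
  }
  missing <- setdiff(.AA20, res)
  if (length(missing)) {
    .teaoStop("teao_schema_error", paste0(
      "property table is missing residue(s): ",
      paste(missing, collapse = ", ")))
  }
  extra <- setdiff(res, .AA20)
  if (length(extra)) {
    .teaoStop("teao_schema_error", paste0(
      "unknown residue row(s): ", paste(extra, collapse = ", ")))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  for (j in seq_len(ncol(vals))) {
    numeric_j <- suppressWarnings(as.numeric(vals[, j]))
    bad <- which(!is.finite(numeric_j))
    if (length(bad)) {
      .teaoStop("teao_schema_error", sprintf(
        "non-numeric value '%s' at row %d, column '%s'",
        vals[bad[1L], j], bad[1L], colnames(vals)[j]))
    }
  }
  storage.mode(vals) <- "double"
  rownames(vals) <- res
  vals <- vals[.AA20, , drop = FALSE]
  dnames <- colnames(vals)
  if (is.null(name)) {
    name <- sub("\\.[^.]*$", "", basename(path))
  }
  labels <- ifelse(dnames %in% names(.ZSCALE_LABELS),
                   .ZSCALE_LABELS[dnames], dnames)
  new("PropertyTable", name = name, values = vals,
      descriptorNames = dnames, descriptorLabels = unname(labels))
}

#' Write a property table as TSV
#'
#' Round-trips through [loadPropertyTable()].
#'
#' @param table A [PropertyTable-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writePropertyTable <- function(table, path) {
  df <- data.frame(residue = rownames(table@values), table@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTsv(df, path)
}

#' @rdname PropertyTable-class
#' @param x A `PropertyTable`.
#' @export
propertyValues <- function(x) x@values

#' @rdname PropertyTable-class
#' @export
setMethod("descriptorNames", "PropertyTable", function(x) x@descriptorNames)

setMethod("show", "PropertyTable", function(object) {
  cat(sprintf("PropertyTable '%s': 20 residues x %d descriptors (%s)\n",
              object@name, ncol(object@values),
              paste(object@descriptorNames, collapse = ", ")))
})

#' Per-column descriptor standard-deviation profile
#'
#' For each column and descriptor, the population standard deviation
#' (divide by n) of the descriptor values over the residue occurrences in
#' that column: each sequence's residue contributes once, so the profile is
#' frequency-weighted; gaps and ambiguity codes contribute nothing. Columns
#' with fewer than two scored residues are flagged and carry 0. Positions
#' with greater physicochemical diversity show higher values.
#'
#' @param x A [ProteinMSA-class].
#' @param table A [PropertyTable-class] (default [builtinZscales()]).
#' @param weighting `"occurrence"` (default) weights by residue frequency;
#'   `"distinct"` scores the set of distinct residues once each
#'   (sensitivity-analysis mode).
#' @return A [PropertyProfile-class].
#' @export
propertySdProfile <- function(x, table = builtinZscales(),
                              weighting = c("occurrence", "distinct")) {
  weighting <- match.arg(weighting)
  arr <- .countsArray(.codeMatrix(x))
  cnt <- arr$counts
  present <- rownames(cnt)[rowSums(cnt) > 0L]
  uncovered <- setdiff(present, rownames(table@values))
  if (length(uncovered)) {
    r <- uncovered[1L]
    .teaoStop("teao_coverage_error", sprintf(
      "property table '%s' lacks residue '%s' (first seen at column %d)",
      table@name, r, which(cnt[r, ] > 0L)[1L]))
  }
  w <- if (weighting == "occurrence") cnt else (cnt > 0L) * 1
  V <- table@values[rownames(cnt), , drop = FALSE]
  n <- colSums(w)
  denom <- pmax(n, 1)
  # two-pass (centered) population SD: exact zeros for uniform columns
  m1 <- crossprod(w, V) / denom          # L x D weighted mean
  sd <- matrix(0, ncol(cnt), ncol(V))
  for (dd in seq_len(ncol(V))) {
    dev2 <- outer(V[, dd], m1[, dd], `-`)^2   # 20 x L squared deviations
    sd[, dd] <- sqrt(colSums(w * dev2) / denom)
  }
  low <- n < 2
  sd[low, ] <- 0
  colnames(sd) <- table@descriptorNames
  rownames(sd) <- NULL
  new("PropertyProfile", sd = sd, descriptorNames = table@descriptorNames,
      lowSupport = unname(low), tableName = table@name)
}

#' @rdname PropertyProfile-class
#' @export
setMethod("sdMatrix", "PropertyProfile", function(x) x@sd)

#' @rdname PropertyProfile-class
#' @export
setMethod("descriptorNames", "PropertyProfile", function(x) x@descriptorNames)

#' @rdname PropertyProfile-class
#' @export
setMethod("lowSupport", "PropertyProfile", function(x) x@lowSupport)

#' @rdname PropertyProfile-class
#' @export
setMethod("nColumns", "PropertyProfile", function(x) nrow(x@sd))

setMethod("show", "PropertyProfile", function(object) {
  cat(sprintf("PropertyProfile ('%s'): %d columns x %d descriptors\n",
              object@tableName, nrow(object@sd), ncol(object@sd)))
})
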