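# taxonomy: lineage annotation and taxon filtering from local NCBI-style
# dump files. Parsing only -- downloading is out of scope, so everything is
# testable offline against tiny synthetic dumps.

#' Load a taxonomy store from local NCBI-style dump files
#'
#' Parses an accession-to-taxid mapping (tab-separated with a header, the
#' NCBI `accession2taxid` dialect: an `accession` and a `taxid` column,
#' located case-insensitively) plus `nodes.dmp` and `names.dmp`
#' (`\\t|\\t`-delimited; names restricted to the scientific-name class).
#' Malformed lines are counted and reported; they are fatal only above
#' `maxMalformedFraction`. Every node's parent chain is verified to reach
#' the root (the taxid whose parent is itself); a cycle raises
#' `teao_cycle_error`.
#'
#' @param accession2taxidPath,nodesPath,namesPath Paths to the three dumps.
#' @param maxMalformedFraction Tolerated fraction of malformed lines per
#'   file (default 0.1).
#' @return A [TaxonomyStore-class].
#' @export
loadTaxonomyStore <- function(accession2taxidPath, nodesPath, namesPath,
                              maxMalformedFraction = 0.1) {
  for (p in c(accession2taxidPath, nodesPath, namesPath)) {
    if (!file.exists(p)) {
      .teaoStop("teao_io_error", paste0("taxonomy file not found: ", p))
    }
  }
  checkMalformed <- function(nBad, nTot, what) {
    if (nBad > 0) {
      message(nBad, " malformed line(s) skipped in ", what)
    }
    if (nTot > 0 && nBad / nTot > maxMalformedFraction) {
      .teaoStop("teao_format_error", sprintf(
        "%d of %d lines malformed in %s (threshold %.0f%%)",
        nBad, nTot, what, 100 * maxMalformedFraction))
    }
  }

  # accession2taxid: TSV with header
  accLines <- readLines(accession2taxidPath)
  if (!length(accLines)) {
    .teaoStop("teao_format_error", "empty accession2taxid file")
  }
  header <- tolower(strsplit(accLines[1L], "\t", fixed = TRUE)[[1L]])
  accCol <- which(header == "accession")[1L]
  taxCol <- which(header == "taxid")[1L]
  if (is.na(accCol) || is.na(taxCol)) {
    .teaoStop("teao_format_error",
              "accession2taxid header must contain 'accession' and 'taxid'")
  }
  fields <- strsplit(accLines[-1L], "\t", fixed = TRUE)
  need <- max(accCol, taxCol)
  okLen <- lengths(fields) >= need
  acc <- vapply(fields[okLen], `[[`, "", accCol)
  tax <- suppressWarnings(
    as.integer(vapply(fields[okLen], `[[`, "", taxCol)))
  okTax <- !is.na(tax)
  checkMalformed(sum(!okLen) + sum(!okTax), length(fields), "accession2taxid")
  accessionToTaxid <- tax[okTax]
  names(accessionToTaxid) <- acc[okTax]

  # nodes.dmp: taxid | parent | rank | ...
  splitDmp <- function(path) {
    lines <- sub("\t\\|$", "", readLines(path))
    strsplit(lines, "\t|\t", fixed = TRUE)
  }
  nodes <- splitDmp(nodesPath)
  okN <- lengths(nodes) >= 3L
  taxids <- suppressWarnings(as.integer(vapply(nodes[okN], `[[`, "", 1L)))
  parents <- suppressWarnings(as.integer(vapply(nodes[okN], `[[`, "", 2L)))
  ranks <- vapply(nodes[okN], `[[`, "", 3L)
  okV <- !is.na(taxids) & !is.na(parents)
  checkMalformed(sum(!okN) + sum(!okV), length(nodes), "nodes.dmp")
  parent <- parents[okV]
  names(parent) <- taxids[okV]
  rank <- ranks[okV]
  names(rank) <- taxids[okV]

  # names.dmp: taxid | name | unique name | class
  nm <- splitDmp(namesPath)
  okM <- lengths(nm) >= 4L
  checkMalformed(sum(!okM), length(nm), "names.dmp")
  nm <- nm[okM]
  cls <- vapply(nm, `[[`, "", 4L)
  sci <- nm[cls == "scientific name"]
  sciName <- vapply(sci, `[[`, "", 2L)
  names(sciName) <- vapply(sci, `[[`, "", 1L)

  roots <- names(parent)[parent == as.integer(names(parent))]
  if (!length(roots)) {
    .teaoStop("teao_format_error",
              "no root taxid (parent of itself) found in nodes.dmp")
  }
  store <- new("TaxonomyStore", accessionToTaxid = accessionToTaxid,
               parent = parent, rank = rank, sciName = sciName,
               rootTaxid = as.integer(roots[1L]))
  # cycle guard: every node must reach the root
  for (t in as.integer(names(parent))) {
    .lineageTaxids(store, t)
  }
  store
}

# root -> leaf chain of taxids; errors on cycles or truncated chains
.lineageTaxids <- function(store, taxid, maxSteps = 100L) {
  chain <- integer(0L)
  cur <- taxid
  for (step in seq_len(maxSteps)) {
    chain <- c(cur, chain)
    p <- store@parent[as.character(cur)]
    if (is.na(p)) {
      .teaoStop("teao_format_error", sprintf(
        "taxid %d has no entry in nodes.dmp", cur))
    }
    if (p == cur) {
      return(chain)
    }
    if (p %in% chain) {
      .teaoStop("teao_cycle_error", sprintf(
        "cycle in taxonomy parents involving taxid %d", cur))
    }
    cur <- unname(p)
  }
  .teaoStop("teao_cycle_error", sprintf(
    "lineage of taxid %d did not reach the root within %d steps",
    taxid, maxSteps))
}

#' Extract the accession from a sequence identifier
#'
#' Default dialect: UniProt-style `db|ACCESSION|name` identifiers yield the
#' middle field, anything else is used whole; a trailing version suffix
#' (`.1`) is stripped in both cases.
#'
#' @param ids Character vector of sequence identifiers.
#' @return Character vector of accessions.
#' @examples
#' extractAccession("sp|Q6GQQ9|OTU7B_HUMAN")  # "Q6GQQ9"
#' @export
extractAccession <- function(ids) {
  acc <- ifelse(grepl("^[A-Za-z]{1,4}\\|[^|]+\\|", ids),
                sub("^[A-Za-z]{1,4}\\|([^|]+)\\|.*$", "\\1", ids),
                ids)
  sub("\\.\\d+$", "", acc)
}

#' Annotate alignment sequences with taxonomic lineages
#'
#' Every identifier is either mapped (accession found in the store) or
#' listed as unmapped; unmapped sequences are reported, never dropped.
#'
#' @param x A [ProteinMSA-class].
#' @param store A [TaxonomyStore-class].
#' @param accessionExtractor Function mapping identifiers to accessions
#'   (default [extractAccession()]).
#' @return A [LineageAnnotation-class].
#' @export
annotateLineages <- function(x, store,
                             accessionExtractor = extractAccession) {
  ids <- seqIds(x)
  acc <- accessionExtractor(ids)
  taxid <- store@accessionToTaxid[acc]
  names(taxid) <- ids
  lineages <- list()
  for (i in which(!is.na(taxid))) {
    chain <- .lineageTaxids(store, unname(taxid[i]))
    key <- as.character(chain)
    lineages[[ids[i]]] <- data.frame(
      taxid = chain,
      rank = unname(ifelse(is.na(store@rank[key]), "no rank",
                           store@rank[key])),
      name = unname(ifelse(is.na(store@sciName[key]), as.character(chain),
                           store@sciName[key])),
      stringsAsFactors = FALSE)
  }
  unmapped <- ids[is.na(taxid)]
  if (length(unmapped)) {
    message(length(unmapped), " identifier(s) without taxonomy mapping")
  }
  new("LineageAnnotation", ids = ids, taxid = as.integer(taxid),
      lineages = lineages, unmapped = unmapped)
}

#' @rdname LineageAnnotation-class
#' @param x A `LineageAnnotation`.
#' @export
unmappedIds <- function(x) x@unmapped

#' @rdname LineageAnnotation-class
#' @export
lineageOf <- function(x, id) x@lineages[[id]]

#' @rdname LineageAnnotation-class
#' @param ... Ignored.
#' @export
setMethod("as.data.frame", "LineageAnnotation", function(x, ...) {
  taxid <- x@taxid
  names(taxid) <- x@ids
  data.frame(
    id = x@ids,
    taxid = unname(taxid),
    lineage = vapply(x@ids, function(id) {
      ln <- x@lineages[[id]]
      if (is.null(ln)) NA_character_ else paste(ln$name, collapse = ";")
    }, ""),
    row.names = NULL, stringsAsFactors = FALSE)
})

setMethod("show", "LineageAnnotation", function(object) {
  cat(sprintf("LineageAnnotation: %d mapped, %d unmapped of %d sequences\n",
              sum(!is.na(object@taxid)), length(object@unmapped),
              length(object@ids)))
})

# TRUE for each id whose lineage contains the taxon (taxid or name)
.lineageContains <- function(ann, taxon) {
  vapply(ann@ids, function(id) {
    ln <- ann@lineages[[id]]
    if (is.null(ln)) {
      return(NA)
    }
    if (is.numeric(taxon)) {
      as.integer(taxon) %in% ln$taxid
    } else {
      taxon %in% ln$name
    }
  }, logical(1L))
}

#' Filter an alignment by taxon
#'
#' Keeps sequences whose lineage contains `include` and, when given, does
#' not contain `exclude`. Original order is preserved; the result must keep
#' at least two sequences.
#'
#' @param x A [ProteinMSA-class].
#' @param ann A [LineageAnnotation-class] for the same alignment.
#' @param include Taxid (numeric) or scientific name to require.
#' @param exclude Optional taxid or name to forbid.
#' @param keepUnmapped Keep sequences without taxonomy mapping
#'   (default `FALSE`).
#' @return A filtered [ProteinMSA-class].
#' @export
filterByTaxon <- function(x, ann, include, exclude = NULL,
                          keepUnmapped = FALSE) {
  ids <- seqIds(x)
  if (!setequal(ann@ids, ids)) {
    .teaoStop("teao_consistency_error",
              "annotation does not cover the alignment identifiers")
  }
  inc <- .lineageContains(ann, include)[ids]
  keep <- ifelse(is.na(inc), keepUnmapped, inc)
  if (!is.null(exclude)) {
    exc <- .lineageContains(ann, exclude)[ids]
    keep <- keep & !ifelse(is.na(exc), FALSE, exc)
  }
  if (sum(keep) < 2L) {
    .teaoStop("teao_size_error", sprintf(
      paste0("taxon filter keeps %d sequence(s); at least 2 are required ",
             "(relax the filter or set keepUnmapped = TRUE)"), sum(keep)))
  }
  x[which(keep)]
}
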