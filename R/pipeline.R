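# One-shot pipeline: MSA -> distances -> UPGMA -> partitions -> profiles ->
# screening -> figure, with every output written to a directory. The whole
# pipeline is deterministic; nothing after the fixture generator consumes
# randomness, so identical inputs and configuration yield byte-identical
# tabular outputs.

.defaultConfig <- function() {
  list(
    input = NULL,
    reference_id = NULL,
    gap_as_symbol = FALSE,
    level_set = "coarse",
    property_table = "builtin",
    property_weighting = "occurrence",
    taxonomy = list(accession2taxid = NULL, nodes = NULL, names = NULL,
                    include = NULL, exclude = NULL, keep_unmapped = FALSE),
    screening = list(min_distinct = 10L, entropy_metric = "global",
                     entropy_threshold = NULL, entropy_quantile = 0.75,
                     terminal_exclusion = 10L, exclusion_file = NULL),
    figure = list(format = "pdf", dpi = 150, column_range = NULL,
                  panels = setdiff(.ALL_PANELS, "two_entropies_scatter")),
    write_distances = FALSE,
    output_dir = "teao_output",
    log_level = "info")
}

#' Read a run configuration file
#'
#' YAML with the keys of the resolved configuration that [runTeao()] writes
#' next to its outputs; missing keys take their defaults, so a resolved
#' config file re-runs losslessly.
#'
#' @param path YAML config path.
#' @return A named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) {
    .teaoStop("teao_io_error", paste0("config file not found: ", path))
  }
  user <- yaml::read_yaml(path)
  cfg <- modifyList(.defaultConfig(), user)
  cfg
}

.logLine <- function(logPath, level, msg, logLevel = "info") {
  line <- paste0("[", level, "] ", msg)
  if (!(logLevel == "warn" && level == "info")) {
    message(line)
  }
  cat(line, "\n", sep = "", file = logPath, append = TRUE)
}

#' Run the full two-entropies pipeline
#'
#' Reads (or accepts) an alignment, optionally filters it by taxon, builds
#' the distance matrix and UPGMA tree, computes the entropy and property
#' profiles, screens candidate positions and renders the overview figure.
#' All outputs land in `outputDir`: `tree.nwk`, `profile.tsv`,
#' `candidates.tsv`, the figure with its sidecar panel tables,
#' `resolved-config.yaml` (lossless re-run input), `run.log`, and
#' optionally `distances.tsv` and `annotation.tsv`.
#'
#' @param input Path to an aligned FASTA file, or a [ProteinMSA-class].
#' @param outputDir Output directory (created; default from config).
#' @param config Optional config list (see [readRunConfig()]); `...`
#'   entries override it.
#' @param ... Individual config overrides, e.g. `reference_id = "sp1"`,
#'   `level_set = "all"`, `screening = list(min_distinct = 8)`.
#' @return Invisibly, a list: `paths` (named output paths) and the computed
#'   objects `msa`, `tree`, `partitions`, `entropy`, `properties`,
#'   `candidates`.
#' @export
runTeao <- function(input, outputDir = NULL, config = list(), ...) {
  cfg <- modifyList(.defaultConfig(), config)
  cfg <- modifyList(cfg, list(...))
  if (!is.null(outputDir)) {
    cfg$output_dir <- outputDir
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(cfg$output_dir, "run.log")
  cat("", file = logPath)  # truncate
  log <- function(level, msg) .logLine(logPath, level, msg, cfg$log_level)
  log("info", paste0("teao ", as.character(packageVersion("teao"))))

  if (is(input, "ProteinMSA")) {
    msa <- input
    cfg$input <- "<in-memory alignment>"
  } else {
    cfg$input <- input
    msa <- readMsa(input)
  }
  log("info", sprintf("alignment: %d sequences x %d columns",
                      nSequences(msa), nColumns(msa)))

  paths <- list()
  tx <- cfg$taxonomy
  if (!is.null(tx$accession2taxid)) {
    store <- loadTaxonomyStore(tx$accession2taxid, tx$nodes, tx$names)
    ann <- annotateLineages(msa, store)
    if (length(unmappedIds(ann))) {
      log("warn", sprintf("%d sequence(s) without taxonomy mapping",
                          length(unmappedIds(ann))))
    }
    paths$annotation <- file.path(cfg$output_dir, "annotation.tsv")
    .writeTsv(as.data.frame(ann), paths$annotation)
    if (!is.null(tx$include)) {
      before <- nSequences(msa)
      msa <- filterByTaxon(msa, ann, include = tx$include,
                           exclude = tx$exclude,
                           keepUnmapped = isTRUE(tx$keep_unmapped))
      log("info", sprintf("taxon filter kept %d of %d sequences",
                          nSequences(msa), before))
    }
  }

  refId <- cfg$reference_id
  if (is.null(refId)) {
    refId <- seqIds(msa)[1L]
    log("info", paste0("no reference id given; using first record '",
                       refId, "'"))
  }
  map <- mapReferencePositions(msa, refId)
  cfg$reference_id <- refId

  d <- pairwiseDistance(msa)
  if (isTRUE(cfg$write_distances)) {
    paths$distances <- file.path(cfg$output_dir, "distances.tsv")
    writeDistanceMatrix(d, paths$distances)
  }
  tree <- upgmaTree(d)
  paths$tree <- file.path(cfg$output_dir, "tree.nwk")
  writeNewick(tree, paths$tree)
  partitions <- treeLevels(tree)

  levelSet <- cfg$level_set
  if (is.character(levelSet) && length(levelSet) == 1L &&
      grepl("^[0-9,:-]+$", levelSet)) {
    levelSet <- .parseLevelSpec(levelSet)
  }
  entropy <- teaoProfile(msa, partitions, levels = levelSet,
                         gapAsSymbol = isTRUE(cfg$gap_as_symbol))
  if (any(lowSupport(entropy))) {
    log("warn", sprintf("%d low-support column(s) (fewer than 2 residues)",
                        sum(lowSupport(entropy))))
  }

  table <- if (identical(cfg$property_table, "builtin")) {
    builtinZscales()
  } else {
    loadPropertyTable(cfg$property_table)
  }
  log("info", paste0("property table: ", table@name))
  properties <- propertySdProfile(msa, table,
                                  weighting = cfg$property_weighting)

  paths$profile <- file.path(cfg$output_dir, "profile.tsv")
  .writeTsv(profileTable(entropy, map = map, properties = properties),
            paths$profile)

  sc <- cfg$screening
  exclusions <- if (!is.null(sc$exclusion_file)) {
    readExclusionList(sc$exclusion_file)
  } else {
    integer(0L)
  }
  candidates <- screenPositions(
    entropy, map, msa, properties = properties,
    minDistinct = sc$min_distinct,
    entropyMetric = sc$entropy_metric,
    entropyThreshold = sc$entropy_threshold,
    entropyQuantile = sc$entropy_quantile,
    terminalExclusion = sc$terminal_exclusion,
    exclusionPositions = exclusions)
  paths$candidates <- file.path(cfg$output_dir, "candidates.tsv")
  .writeTsv(candidates, paths$candidates)
  log("info", sprintf("screening: %d of %d positions pass",
                      sum(candidates$pass), nrow(candidates)))

  fg <- cfg$figure
  figPaths <- renderOverview(
    msa, entropy, properties = properties, tree = tree, map = map,
    panels = fg$panels, columnRange = fg$column_range,
    dir = cfg$output_dir, basename = "overview",
    format = fg$format, dpi = fg$dpi)
  paths$figure <- figPaths[1L]
  paths$panel_tables <- figPaths[-1L]

  cfg$zscale_table <- table@name
  cfg$teao_version <- as.character(packageVersion("teao"))
  paths$config <- file.path(cfg$output_dir, "resolved-config.yaml")
  yaml::write_yaml(cfg, paths$config)
  paths$log <- logPath
  log("info", "done")

  invisible(list(paths = paths, msa = msa, tree = tree,
                 partitions = partitions, entropy = entropy,
                 properties = properties, candidates = candidates))
}

# "1:8" or "1,2,5" or "3" -> integer level vector
.parseLevelSpec <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1L]]
  out <- integer(0L)
  for (p in parts) {
    if (grepl("^\\d+[:-]\\d+$", p)) {
      ab <- as.integer(strsplit(p, "[:-]")[[1L]])
      out <- c(out, seq(ab[1L], ab[2L]))
    } else if (grepl("^\\d+$", p)) {
      out <- c(out, as.integer(p))
    } else {
      .teaoStop("teao_config_error", paste0("cannot parse level set: ", s))
    }
  }
  sort(unique(out))
}
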