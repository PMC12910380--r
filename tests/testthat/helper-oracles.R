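# Shared fixtures and independent brute-force oracles. The oracles never
# share code paths with the implementation they check: UPGMA recomputes
# between-cluster averages from the original matrix at every step, entropy
# and property SDs are recomputed per column from first principles.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

makeMsa <- function(...) ProteinMSA(c(...))

randomDistMatrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2)
  d <- d + t(d)
  rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  d
}

# canonical form of a partition: a sorted set of sorted member-id sets
canonicalPartition <- function(memb) {
  sort(unname(vapply(split(names(memb), memb),
                     function(s) paste(sort(s), collapse = "|"), "")))
}

# Brute-force UPGMA: average distances recomputed from the original matrix
# between full member sets at every step (O(N^3)); same tie rule as the
# production code (lexicographically smallest founding-index pair).
oracleUpgma <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1L)
  parts <- vector("list", n)
  memb <- integer(n)
  names(memb) <- labels
  snapshot <- function() {
    for (g in seq_along(clusters)) memb[clusters[[g]]] <<- g
    canonicalPartition(memb)
  }
  parts[[n]] <- snapshot()
  for (m in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        f <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        better <- is.null(best) || avg < best$avg ||
          (avg == best$avg &&
             (f[1L] < best$f[1L] ||
                (f[1L] == best$f[1L] && f[2L] < best$f[2L])))
        if (better) {
          best <- list(avg = avg, f = f, i = i, j = j)
        }
      }
    }
    heights[m] <- best$avg / 2
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    parts[[n - m]] <- snapshot()
  }
  list(heights = heights, partitions = parts)
}

# per-column entropy from scratch
oracleEntropy <- function(column) {
  chars <- column[column %in% AA20]
  if (length(chars) <= 1L) {
    return(0)
  }
  p <- table(chars) / length(chars)
  -sum(p * log2(p))
}

# per-column population SD of one descriptor, occurrences or distinct set
oracleSd <- function(column, values, weighting = "occurrence") {
  chars <- column[column %in% AA20]
  if (weighting == "distinct") {
    chars <- unique(chars)
  }
  if (length(chars) < 2L) {
    return(0)
  }
  v <- values[chars]
  sqrt(mean((v - mean(v))^2))
}

# tiny synthetic NCBI-style dump files; returns the three paths.
# Tree: 1 (root) -> 2 Bacteria -> 561 Escherichia -> 562 E. coli
#                -> 2759 Eukaryota -> 9606 Homo sapiens
writeTaxonomyFixture <- function(dir) {
  acc <- file.path(dir, "acc2taxid.tsv")
  writeLines(c(
    "accession\taccession.version\ttaxid\tgi",
    "ECA1\tECA1.1\t562\t1001",
    "ECA2\tECA2.2\t562\t1002",
    "ECA3\tECA3.1\t561\t1003",
    "HSA1\tHSA1.1\t9606\t1004",
    "Q6GQQ9\tQ6GQQ9.1\t9606\t1005"), acc)
  nodes <- file.path(dir, "nodes.dmp")
  writeLines(c(
    "1\t|\t1\t|\tno rank\t|",
    "2\t|\t1\t|\tsuperkingdom\t|",
    "561\t|\t2\t|\tgenus\t|",
    "562\t|\t561\t|\tspecies\t|",
    "2759\t|\t1\t|\tsuperkingdom\t|",
    "9606\t|\t2759\t|\tspecies\t|"), nodes)
  names <- file.path(dir, "names.dmp")
  writeLines(c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
    "2\t|\teubacteria\t|\t\t|\tsynonym\t|",
    "561\t|\tEscherichia\t|\t\t|\tscientific name\t|",
    "562\t|\tEscherichia coli\t|\t\t|\tscientific name\t|",
    "2759\t|\tEukaryota\t|\t\t|\tscientific name\t|",
    "9606\t|\tHomo sapiens\t|\t\t|\tscientific name\t|"), names)
  list(acc = acc, nodes = nodes, names = names)
}

# Constructed screening toy: 12 sequences x 30 columns, reference ungapped.
# Exactly columns 14 and 15 carry >= 10 distinct residues away from the
# termini; column 3 is a high-diversity terminal plant, column 17 a
# 3-residue column, column 20 has 8 distinct residues.
buildScreeningToy <- function() {
  n <- 12L
  m <- matrix("A", n, 30L)
  div1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N")
  div2 <- c("P", "Q", "R", "S", "T", "V", "W", "Y", "A", "C", "D", "E")
  m[, 14] <- div1
  m[, 15] <- div2
  m[, 3] <- div1                              # terminal plant
  m[, 17] <- rep(c("C", "D", "E"), each = 4)  # 3 distinct
  m[, 20] <- rep(div1[1:8], length.out = n)   # 8 distinct
  seqs <- apply(m, 1, paste, collapse = "")
  names(seqs) <- sprintf("s%02d", seq_len(n))
  ProteinMSA(seqs)
}

toyProfiles <- function(msa) {
  ps <- treeLevels(upgmaTree(pairwiseDistance(msa)))
  list(entropy = teaoProfile(msa, ps),
       map = mapReferencePositions(msa, "s01"),
       props = propertySdProfile(msa))
}
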