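Package: teao
Title: Two-Entropies Analysis of Protein Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects specificity-determining and rheostat-candidate positions
    in protein families from a single multiple sequence alignment. Implements
    Two-Entropies Analysis in its objective (tree-derived) form: per-column
    Shannon entropy is computed globally and averaged within subgroups taken
    from the levels of a deterministic UPGMA dendrogram, yielding
    conservation and specificity scores per alignment column. Adds
    physicochemical variability profiles based on z-scale amino-acid
    descriptors (with pluggable custom property tables), taxonomy-aware
    filtering of alignments from local NCBI-style dump files, a rule-based
    residue screening report, a planted-signal synthetic alignment generator
    for validation, and a multi-panel per-position overview figure with
    machine-readable sidecar tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Biostrings,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Alignment, MultipleSequenceAlignment, Phylogenetics, Visualization
RoxygenNote: 7.3.3
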