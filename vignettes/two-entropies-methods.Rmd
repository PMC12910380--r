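---
title: "Two-Entropies Analysis: model, choices and limitations"
author: "teao package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-Entropies Analysis: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teao)
```

## The model

A column of a protein multiple sequence alignment (MSA) is summarised by
the Shannon entropy of its residue distribution,

$$H[c] \;=\; -\sum_{a} p_a[c]\,\log_2 p_a[c] \qquad (\text{bits}),$$

where $p_a[c]$ is the frequency of residue $a$ among the standard residues
observed in column $c$. $H = 0$ marks a fully conserved column and
$H = \log_2 20 \approx 4.32$ a maximally variable one.

Two-Entropies Analysis contrasts this *global* entropy with the entropy
computed *within subgroups* of the family. A specificity-determining
position is conserved inside each subgroup but differs between subgroups:
its global entropy is high while its within-subgroup entropy is low. In the
objective (tree-derived) variant the subgroups are not chosen by the user.
A UPGMA dendrogram is built from pairwise p-distances, and cutting it
between consecutive merge heights yields one partition per level $k$: the
whole family at $k = 1$ down to singletons at $k = N$. At each level the
within-subgroup entropies are combined size-weighted,

$$H_k[c] \;=\; \sum_g \frac{n_g}{N} H_g[c],$$

which guarantees $H_k[c] \le H_{\mathrm{global}}[c]$ (concavity of entropy
under mixture). The averaged entropy $H_{\mathrm{avg}}[c]$ is the
unweighted mean of $H_k[c]$ over a selected set of levels, and two scores
are derived:

$$\mathrm{conservation}[c] = 1 - \frac{H_{\mathrm{global}}[c]}{\log_2 A},
\qquad
\mathrm{specificity}[c] =
\frac{H_{\mathrm{global}}[c] - H_{\mathrm{avg}}[c]}{\log_2 A},$$

with $A$ the alphabet size (20, or 21 when gaps are counted as a symbol).
Both lie in $[0, 1]$.

### Assumptions

* Columns are treated independently; no coevolution or sequence weighting.
* The p-distance tree is a clustering device, not a phylogeny: no
  substitution model, no rate variation, no rooting options.
* Subfamily structure is assumed to be expressible as a nested partition
  chain (UPGMA's ultrametric hierarchy).

## Which tree levels enter the average

The level set is the one genuinely open design choice, and it matters.
Averaging over *all* $N$ levels looks natural but has a degenerate limit:
for $k$ close to $N$ almost every subgroup is a singleton or near-singleton
whose entropy is trivially 0, so $H_{\mathrm{avg}}$ collapses toward 0 for
*every* variable column. The difference
$H_{\mathrm{global}} - H_{\mathrm{avg}}$ then ranks columns essentially by
global entropy alone, and unstructured high-entropy columns outscore true
subfamily-specific ones. On synthetic families generated by
`simulateMsa()` this is not a marginal effect: with 4 subfamilies of 8
sequences, planted specific columns score about 0.44 while i.i.d.-random
columns reach about 0.65 under all-level averaging.

`teaoProfile()` therefore defaults to `levels = "coarse"`, the levels
$k = 1, \dots, \lceil\sqrt{N}\rceil$. The square-root cap is scale-free,
keeps every averaged level at a mean subgroup size of at least $\sqrt{N}$
sequences (so within-subgroup entropies are informative), and comfortably
covers the number of biologically distinct subfamilies realistic samples
contain. Under the same synthetic conditions the planted specific columns
then outrank all background columns, which is exactly the behaviour the
score is meant to have; the package's test suite computes this. `"all"`
(every level) and `"trimmed"` ($2..N-1$), as well as explicit level
vectors, remain available for comparison with other implementations.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gapAsSymbol` | `FALSE` | Gaps excluded from entropy distributions; gap fraction reported separately. Counting gaps as a 21st symbol inflates entropy at ragged alignment edges, but the switch exists because some workflows expect it (the normalizer becomes $\log_2 21$). |
| `levels` | `"coarse"` | See above. |
| `weighting` (property profile) | `"occurrence"` | The standard deviation of each z-scale is taken over residue *occurrences* (each sequence contributes once), i.e. the column's actual distribution. `"distinct"` scores the set of distinct residues once each, as a sensitivity check. |
| `minDistinct` (screening) | 10 | Minimum number of distinct substitutions for a candidate position. |
| `entropyQuantile` (screening) | 0.75 | "High entropy" has no canonical absolute value, so the default threshold is the top quartile of the metric over reference-mapped columns; an absolute `entropyThreshold` (bits) overrides it. |
| `terminalExclusion` (screening) | 10 | Residues trimmed from each reference end; terminal columns are alignment-quality artifacts more often than signal. |

Population (divide-by-$n$) standard deviations are used for the property
profiles: the column *is* the population of interest. Z-scales 4-5 are
deliberately not shipped; they explain little variance (13% and 6%) and
are hard to interpret. A custom table with any number of descriptors can
be supplied.

## Numerical and degenerate-input conventions

* Columns with at most one counted residue (all-gap or single-sequence
  coverage) get entropy 0 and a low-support flag carried into all outputs,
  rather than NaN.
* Sequence pairs sharing no comparable column get p-distance 1 with a
  warning, so sparse alignments degrade instead of failing.
* UPGMA ties (exactly equal between-cluster averages) are broken by the
  lexicographically smallest pair of founding indices (the smallest
  original record index in each cluster). The tree is therefore
  bit-reproducible for a given input order; with distinct distances the
  partitions are also invariant under record permutation.
* Property-profile standard deviations are computed with the two-pass
  (centered) formula so fully uniform columns give exactly 0.
* Consensus ties are broken alphabetically.
* The screening table retains failing rows with machine-readable failure
  reasons, so the pass set is auditable and reconstructible.

## What the synthetic generator does and does not emulate

`simulateMsa()` plants four column classes (globally conserved,
subfamily-specific, i.i.d. random, gappy) on a fixed subfamily structure,
with optional uniform substitution noise. It reproduces the features the
method's scores respond to -- nested family structure, per-class column
signatures, missing data -- and it is deliberately *not* a sequence
evolution simulator: there is no substitution-rate matrix, no
phylogenetic correlation along a tree, and no indel process. Passing the
recovery tests therefore shows that the scores separate the planted
signal classes under controlled conditions; it does not certify
performance on real families, where alignment quality, uneven taxon
sampling and correlated sites all intrude. Defaults (4 subfamilies x 8
sequences, 100 columns of which 10 conserved and 10 subfamily-specific,
noise 0 or 0.05) are the conditions used throughout the test suite; the
suite scales other fixtures down to 12-32 sequences and 15-60 columns to
keep the default run fast.

## Taxonomy

Lineage annotation is strictly offline: the three NCBI-style dump dialects
(accession2taxid, `nodes.dmp`, `names.dmp`) are parsed from local files,
lineage walks are cycle-guarded, and unmapped accessions are reported,
never silently dropped. Filtering keeps sequences whose lineage contains
an `include` taxon (id or scientific name) and lacks the `exclude` taxon.
Rebalancing of over-represented taxa is out of scope: no published
procedure is adopted here, and silent subsampling would change the entropy
profiles in ways the user should control.

## Known limitations

* Specificity scores compare a column against the tree of the *whole*
  alignment; heavily duplicated sequences bias both the tree and the
  entropies (no sequence weighting).
* The Newick writer and the level-matrix recursion are comfortable at
  thousands of sequences but have not been tuned for the 10^5 scale.
* `screenPositions()` operates on reference-mapped columns only; insertions
  relative to the reference are never candidates.
* Exact numeric agreement with other Two-Entropies implementations is not
  promised: the level set, distance metric and averaging weights are
  documented choices, and comparable implementations differ in exactly
  these.
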