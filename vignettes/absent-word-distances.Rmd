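---
title: "Absent-word distances: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absent-word distances: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mawdist)
```

## The model

A word `y` is *absent* from a sequence `x` when it occurs in no segment of
`x` as a substring; it is a *minimal absent word* (MAW) when additionally
every proper factor of `y` occurs in `x`. Minimality is what makes the set
informative and small: the full set of absent words is infinite, while the
MAW set of a sequence of length `n` is finite (no MAW is longer than
`n + 1`) and characterizes which extensions of observed context are
forbidden. The package treats MAW sets as the fingerprint of a sequence and
derives pairwise (dis)similarity indexes from pairs of fingerprints:
set-theoretic ones (length-weighted index on the symmetric difference or
intersection, Jaccard), a distributional one (total variation distance
between word-length histograms), compositional ones (GC content of the
difference or intersection), and two based on *minimal relative absent
words* — words present in a target but absent from a reference, kept only
when they contain no shorter such minimal word. Because relative absent
words are directional, the two directed indexes of a pair are averaged,
which restores symmetry.

The enumeration itself uses a simple equivalent characterization: a word of
length `k ≥ 2` is a MAW iff it is absent while its length-`(k-1)` prefix and
suffix are both present; presence of every shorter factor follows because
factors of present words are present. Enumeration therefore walks `k`
upwards over per-length present-`k`-mer tables, extending present
`(k-1)`-mers by one symbol. This is not the asymptotically optimal
suffix-structure algorithm, but for the intended scale (gene-sized inputs,
up to a few tens of kilobases) it is simple, allocation-friendly in R, and
its correctness is pinned to an independent literal-definition oracle
(`bruteForceMaws()`) in the test suite rather than to the construction.

## Strand handling

DNA is double-stranded; a word absent from the forward strand may occur on
the reverse complement. Under the `RC` setting every record is replaced by
itself plus the reverse complements of its segments (in reverse order)
before word sets are computed. Junction words are excluded by construction:
records are *segmented*, factors never span segment boundaries, and the
forward/reverse junction is a boundary. The same segmentation mechanism
handles ambiguous bases: under the default `split` policy a run of
non-alphabet characters (e.g. `N`) becomes a segment boundary, because
absent-word logic is undefined for degenerate symbols. The alternative
`reject` policy refuses such input outright; it is configurable because
curated benchmark sets are typically unambiguous while real assemblies are
not.

## Parameters that matter

* `kMax` (default 24) bounds the word length for minimal relative absent
  words. The published description of the relative-absent-word runs does
  not state the range their enumeration tool used, so reproduction of
  RAW-based matrices is sensitive to this choice. The default reflects
  that the length-weighted index weights a word by `1/k²`: beyond a couple
  dozen characters a word's contribution is negligible relative to the
  short words that dominate the index. The iteration also stops as soon as
  the target has no factors of the current length.
* `maxLen` (default unbounded) optionally caps MAW length; the natural
  bound `n + 1` makes the default safe for gene-scale inputs.
* `topK` (default 3) in `evaluateRelations()` sizes the neighborhoods used
  by the two remoteness relations.

## Operationalizing the six relations

The six expected relations on the 11-species beta-globin benchmark are
qualitative biological statements. The package fixes the weakest
quantitative readings that are checkable on a distance matrix: REL1 as
nearest-neighbor membership (Gorilla and Chimpanzee are Human's two nearest,
in either order), REL2 as mutual nearest neighbors (Goat/Bovine), REL3 as
one-sided nearest neighbor (Mouse nearest to Rat — the reverse direction is
not required), REL4/REL5 as exclusion of Gallus (resp. Opossum) from every
other species' top-3 list, and REL6 as Lemur's mean rank across the other
species' rankings falling in the bottom half (mean position > (n−1)/2 = 5).
These readings were chosen so that the two bundled benchmark matrices give
the verdicts reported for them: the RAW length-weighted matrix satisfies
all six, and the Jaccard matrix satisfies the three core relations. Each
threshold is an argument, so stricter readings are a one-line change.

Neighbor rankings break ties lexicographically (C-locale radix order).
This matters for matrices printed at two decimals: the bundled Jaccard
benchmark contains exact ties, so its published ranking rows are only
reproducible up to permutations within a tied block, and the tests compare
them exactly that way.

## Numerical and degenerate-input conventions

Several indexes have no published value for degenerate inputs; the package
fixes conventions chosen for continuity with the identical-sequence limit
of difference-type measures and for maximal dissimilarity of
intersection-type measures when nothing is shared: `Jaccard(∅, ∅) = 0`; GC
content of an empty symmetric difference is 0; the GC-intersection index of
an empty intersection is 1; an empty relative-absent-word set contributes 0
to the averaged RAW GC index. The total variation distance on an empty word
set is an *error*, not 0 — no length distribution exists, and surfacing
that is safer than a silent convention.

One definitional subtlety: the natural level-by-level recursion for minimal
relative absent words ("exclude words whose length-(k−1) factors meet the
previous minimal set") breaks when an intermediate level is empty — for
target `AAAA` against reference `ACGT` it would exclude `AAA` (contains the
minimal `AA`) but then re-admit `AAAA`, which also contains `AA`. The
package therefore enforces minimality against *all* shorter reported words:
a candidate is kept only if no previously reported minimal word is a factor
of it. This matches the intended meaning (a minimal word of size `k`
contains no minimal word of size less than `k`) and is what the worked
examples and tests pin down.

Distance matrices force a zero diagonal and are symmetrized from the upper
triangle. The intersection length-weighted index is non-positive by design;
since UPGMA and neighbor joining assume non-negative dissimilarities, tree
builders first subtract the global off-diagonal minimum when it is negative
and record the shift in the tree's `"shift"` attribute. Negative estimated
NJ branch lengths are clamped to zero, with pre-clamp values kept in
metadata. Agglomeration uses `stats::hclust` (average linkage) and
`ape::nj`; both are deterministic, so pipeline reruns are byte-identical.

## What the synthetic generator does and does not show

`randomRecords()` draws i.i.d. uniform sequences over the alphabet. This is
the right null model for *correctness* testing: short uniform strings have
rich, irregular absent-word structure, and the suite checks the enumerator
against the literal-definition oracle on hundreds of them (unit tests use
records up to length 12–14; the end-to-end check runs 200 records of length
up to 14 with words searched to length 15 — sizes chosen so the literal
oracle stays fast while still exercising the `n + 1` length bound). Uniform
strings do **not** emulate real DNA: no compositional bias, no repeats, no
shared evolutionary signal. Passing these tests shows the machinery
computes its definitions exactly; it says nothing about how well any index
tracks phylogeny on real data — for that the package ships the published
11-species benchmark matrices, against which the ranking and relation
machinery is validated row by row. Tree-builder consistency is likewise
tested on exactly additive and ultrametric matrices generated from random
trees (100 each, 4–12 leaves, path-length error below 1e−9), which is the
regime where NJ and UPGMA are provably exact.

## Known limitations

* Reproducing the published RAW-based matrices from primary sequences
  requires the original 11-species beta-globin exon-1 FASTA, which is not
  redistributed here, and is sensitive to the unreported `kMax` of the
  original runs.
* The enumerator is in-memory R; it targets gene- to plasmid-scale inputs,
  not whole mammalian genomes.
* Seven measures × two settings are described in the originating analysis
  as 14 matrices; this package splits the RAW index pair into `RAW_LWI`
  and `RAW_GCC`, so requesting all eight measures in both settings yields
  16 matrix artifacts.
* Published tree figures for the benchmark carry no branch lengths, so
  tree topologies are validated against closed forms and simulated
  additive matrices, not against the figures.
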