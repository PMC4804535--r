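# mawdist

Alignment-free (dis)similarity analysis of DNA sequences from **minimal
absent words**.

## The problem and who this is for

Comparing biological sequences without aligning them is attractive whenever
alignment is expensive or ill-defined (rearranged genes, diverged regions,
whole genomes). One family of alignment-free methods looks not at the words
a sequence *contains* but at the words it *lacks*: an **absent word** of a
sequence `x` is a word that never occurs in `x` as a substring, and a
**minimal absent word (MAW)** is an absent word all of whose proper factors
do occur. For `x = abbaab` over `{a, b}`, the words `aaa`, `aba`, `bbb` are
MAWs, while `aaab` is absent but not minimal (it contains the absent `aaa`).
The MAW set is a compact fingerprint of a sequence, and distances between
MAW sets turn out to track evolutionary relatedness.

`mawdist` is for researchers who want to use absent-word statistics as a
distance measure for sequence comparison and distance-based phylogeny
reconstruction, and to compare the available indexes on their own data.

## What it computes

For two sequences `x`, `y` with MAW sets `M_x`, `M_y`:

| Code | Index |
|---|---|
| `LWI_SYM` | length-weighted index of the symmetric difference: `sum over u in M_x Δ M_y of 1/|u|²` |
| `LWI_INT` | negated length-weighted index of the intersection: `− sum over u in M_x ∩ M_y of 1/|u|²` |
| `JACCARD` | Jaccard distance `1 − |M_x ∩ M_y| / |M_x ∪ M_y|` |
| `TVD` | total variation distance `½ Σ_i |P(i) − Q(i)|` between the normalized word-length histograms of the two MAW sets |
| `GCC_SYM` | GC fraction of the characters of `M_x Δ M_y` |
| `GCC_INT` | `1 −` GC fraction of the characters of `M_x ∩ M_y` |
| `RAW_LWI` | average of the length-weighted indexes of the two directed **minimal relative absent word** sets |
| `RAW_GCC` | average of the GC fractions of the two directed RAW sets |

A **relative absent word** of a target `x` with respect to a reference `y`
is a word present in `x` and absent from `y`; the *minimal* ones contain no
shorter minimal relative absent word as a factor.

Each index can be computed in the plain forward-strand setting (`noRC`) or
with every sequence concatenated with its reverse complement (`RC`), with
words spanning the junction excluded; the RC setting captures words that
occur only on the opposite strand.

On top of the indexes the package builds labeled symmetric distance
matrices, ranked nearest-neighbor lists, a six-relation biological sanity
check for the classic 11-species beta-globin first-exon benchmark (primate
clustering; Goat/Bovine and Rat/Mouse pairs; remoteness of Gallus, Opossum
and Lemur), and UPGMA / neighbor-joining trees with Newick export.

## Worked example

```r
library(mawdist)

ab <- binaryAlphabet()
x <- SegmentedSequence("x", "abbaab", ab)
y <- SegmentedSequence("y", "aab", ab)
words(enumerateMaws(x))
#> [1] "aaa"  "aabb" "aba"  "bab"  "bbb"
lwiSymmetricDifference(enumerateMaws(x), enumerateMaws(y))
#> [1] 0.8958333       # = 43/48
jaccardDistance(enumerateMaws(x), enumerateMaws(y))
#> [1] 0.8571429       # = 6/7: the two MAW sets share 1 of 7 words
```

The package ships the published benchmark distance matrices for the first
exon of the beta-globin gene of 11 species (RC setting). Ranking neighbors
and checking the six expected relations:

```r
m <- benchmarkMatrix("RAW_LWI")
rankedNeighbors(m)$Human[1:3]
#> [1] "Gorilla" "Chimp"   "Rabbit"
evaluateRelations(m)
#> RelationReport: 6 of 6 relations satisfied
#>   REL1 [ok] Human's two nearest: Gorilla, Chimp
#>   REL2 [ok] Goat's nearest: Bovine; Bovine's nearest: Goat
#>   REL3 [ok] Rat's nearest: Mouse
#>   REL4 [ok] Gallus in no mammal's top 3
#>   REL5 [ok] Opossum in no other species' top 3
#>   REL6 [ok] Lemur's mean neighbor rank 8.40 (threshold > 5.0)
```

A full end-to-end run over a FASTA file (matrices, rankings, relation
reports, trees) is one call — or one shell command via the thin wrapper in
`inst/scripts/awords.R`:

```r
runPipeline("seqs.fasta", "results/", measures = c("RAW_LWI", "JACCARD"),
            settings = "RC", trees = "NJ")
```

To reproduce the published pairwise values for the benchmark (e.g.
Human–Gorilla Jaccard 0.15 under RC), place the 11-species beta-globin
exon-1 FASTA (available from the original study's data repository; not
redistributed here) at `inst/extdata/beta_globin_exon1.fasta` and re-run
the test suite.

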