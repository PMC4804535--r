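Package: mawdist
Title: Alignment-Free DNA Sequence Comparison with Minimal Absent Words
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free (dis)similarity analysis of DNA sequences based on
    minimal absent words (MAWs) and minimal relative absent words (RAWs).
    Enumerates the minimal absent word set of a (possibly segmented) sequence,
    computes seven length- and content-based indexes on pairs of word sets
    (length-weighted index on the symmetric difference and on the intersection,
    Jaccard distance, total variation distance on word-length histograms, GC
    content on the symmetric difference and on the intersection, and averaged
    length-weighted/GC indexes on relative absent word sets), assembles labeled
    pairwise distance matrices under forward-strand and reverse-complement-aware
    settings, ranks nearest neighbors, evaluates six expected biological
    relations on an 11-species beta-globin benchmark, and reconstructs
    distance-based phylogenies (UPGMA, neighbor joining) with Newick export.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
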