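# Shared fixtures: toy records and the published 11-species benchmark
# neighbor rankings (re-derived from the benchmark matrices and frozen).

binRec <- function(id, s) SegmentedSequence(id, s, binaryAlphabet())
dnaRec <- function(id, s, setting = "noRC")
  SegmentedSequence(id, s, dnaAlphabet(), setting)

writeTempFasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# All k-mer occurrences (with multiplicity) of a segmented record.
kmerMultiset <- function(segs, k) {
  unlist(lapply(segs, function(s) {
    L <- nchar(s)
    if (L < k) character() else substring(s, 1:(L - k + 1L), k:L)
  }), use.names = FALSE)
}

# Published neighbor rankings for the RAW length-weighted-index benchmark
# matrix (RC setting); every row is exact (no ties in that matrix).
rawLwiRankings <- list(
  Human   = c("Gorilla","Chimp","Rabbit","Bovine","Goat","Mouse","Opossum","Lemur","Rat","Gallus"),
  Goat    = c("Bovine","Gorilla","Human","Gallus","Chimp","Rabbit","Mouse","Lemur","Rat","Opossum"),
  Opossum = c("Rabbit","Gorilla","Human","Bovine","Chimp","Goat","Mouse","Gallus","Rat","Lemur"),
  Gallus  = c("Goat","Bovine","Rabbit","Gorilla","Human","Lemur","Opossum","Mouse","Chimp","Rat"),
  Lemur   = c("Goat","Bovine","Rabbit","Gorilla","Human","Gallus","Mouse","Chimp","Rat","Opossum"),
  Mouse   = c("Gorilla","Bovine","Chimp","Human","Rabbit","Goat","Rat","Opossum","Lemur","Gallus"),
  Rabbit  = c("Gorilla","Human","Chimp","Bovine","Mouse","Goat","Gallus","Opossum","Lemur","Rat"),
  Rat     = c("Mouse","Goat","Human","Bovine","Gorilla","Rabbit","Chimp","Opossum","Gallus","Lemur"),
  Gorilla = c("Human","Chimp","Rabbit","Bovine","Mouse","Goat","Opossum","Lemur","Gallus","Rat"),
  Bovine  = c("Goat","Gorilla","Human","Chimp","Rabbit","Mouse","Lemur","Gallus","Rat","Opossum"),
  Chimp   = c("Human","Gorilla","Rabbit","Bovine","Mouse","Goat","Opossum","Rat","Lemur","Gallus"))

# Published neighbor rankings for the Jaccard benchmark matrix (RC setting);
# that matrix is printed at two decimals and contains ties, so rows are
# compared up to permutations within blocks of equal distance.
jaccardRankings <- list(
  Human   = c("Gorilla","Chimp","Rabbit","Bovine","Mouse","Goat","Lemur","Gallus","Rat","Opossum"),
  Goat    = c("Bovine","Gorilla","Human","Chimp","Lemur","Gallus","Rabbit","Mouse","Rat","Opossum"),
  Opossum = c("Chimp","Human","Gorilla","Rabbit","Goat","Gallus","Bovine","Lemur","Rat","Mouse"),
  Gallus  = c("Goat","Rabbit","Human","Gorilla","Chimp","Bovine","Lemur","Mouse","Opossum","Rat"),
  Lemur   = c("Bovine","Goat","Gorilla","Human","Chimp","Rabbit","Rat","Gallus","Mouse","Opossum"),
  Mouse   = c("Gorilla","Chimp","Human","Bovine","Goat","Rat","Rabbit","Gallus","Lemur","Opossum"),
  Rabbit  = c("Human","Gorilla","Chimp","Bovine","Goat","Mouse","Gallus","Lemur","Rat","Opossum"),
  Rat     = c("Mouse","Goat","Human","Gorilla","Rabbit","Lemur","Chimp","Bovine","Gallus","Opossum"),
  Gorilla = c("Human","Chimp","Rabbit","Mouse","Bovine","Goat","Lemur","Gallus","Rat","Opossum"),
  Bovine  = c("Goat","Gorilla","Human","Chimp","Lemur","Mouse","Rabbit","Gallus","Rat","Opossum"),
  Chimp   = c("Gorilla","Human","Rabbit","Mouse","Bovine","Goat","Lemur","Gallus","Opossum","Rat"))

# TRUE iff `got` equals `want` after allowing permutations among neighbors
# tied at the same distance from `focal` in matrix m.
sameUpToTies <- function(m, focal, got, want) {
  v <- distValues(m)
  setequal(got, want) &&
    isTRUE(all.equal(unname(v[focal, got]), unname(v[focal, want])))
}
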