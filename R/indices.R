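# Pairwise (dis)similarity indexes on word sets.
#
# Conventions for degenerate inputs (identical or disjoint sets), chosen for
# continuity with the identical-sequence limit of difference-type measures
# and maximal dissimilarity of intersection-type measures when nothing is
# shared: Jaccard(empty, empty) = 0; GC content of an empty symmetric
# difference = 0; GC-intersection with an empty intersection = 1; an empty
# RAW set contributes 0 to the averaged RAW GC index. The total variation
# distance is an error (not 0) on an empty word set, because no length
# distribution exists there.

#' Length-weighted index of a word set
#'
#' Sum over the words u of 1/|u|^2; the empty set scores 0. Short absent
#' words are weighted most heavily: a missing short word is a stronger
#' signal than a missing long one.
#'
#' @param ws a [WordSet-class] (or plain character vector of words).
#' @return non-negative numeric.
#' @examples
#' lwi(c("C", "G", "T"))  # 3
#' @export
lwi <- function(ws) {
  w <- if (is(ws, "WordSet")) ws@words else ws
  if (!length(w)) return(0)
  sum(1 / nchar(w)^2)
}

checkComparable <- function(mx, my) {
  stopifnot(is(mx, "WordSet"), is(my, "WordSet"))
  if (!identical(mx@alphabet@symbols, my@alphabet@symbols))
    stop("word sets are over different alphabets")
  if (mx@setting != my@setting)
    stop("word sets were computed under different strand settings")
  invisible(TRUE)
}

#' Length-weighted index on the symmetric difference
#'
#' Distance between two sequences as the length-weighted index of the
#' symmetric difference of their minimal absent word sets: words absent
#' from exactly one of the two sequences, weighted by 1/length^2.
#'
#' @param mx,my [WordSet-class] objects over the same alphabet and setting.
#' @return non-negative numeric; 0 when the sets coincide.
#' @export
lwiSymmetricDifference <- function(mx, my) {
  checkComparable(mx, my)
  lwi(c(setdiff(mx@words, my@words), setdiff(my@words, mx@words)))
}

#' Negated length-weighted index on the intersection
#'
#' The shared minimal absent words measure similarity, so the index is the
#' negated length-weighted index of the intersection: more (and shorter)
#' shared words give a more negative, i.e. smaller, value.
#'
#' @inheritParams lwiSymmetricDifference
#' @return non-positive numeric; 0 when the sets are disjoint.
#' @export
lwiIntersection <- function(mx, my) {
  checkComparable(mx, my)
  -lwi(intersect(mx@words, my@words))
}

#' Jaccard distance between word sets
#'
#' One minus intersection-over-union of the two word sets. Two empty sets
#' are at distance 0 (identical-sequence limit).
#'
#' @inheritParams lwiSymmetricDifference
#' @return numeric in \[0, 1\].
#' @export
jaccardDistance <- function(mx, my) {
  checkComparable(mx, my)
  u <- length(union(mx@words, my@words))
  if (u == 0L) return(0)
  1 - length(intersect(mx@words, my@words)) / u
}

#' Total variation distance between word-length histograms
#'
#' Counts words per length in each set, normalizes each histogram to a
#' probability distribution over the union of observed lengths, and returns
#' half the L1 distance between the two distributions. Undefined (an error)
#' when either set is empty.
#'
#' @inheritParams lwiSymmetricDifference
#' @return numeric in \[0, 1\].
#' @export
tvdDistance <- function(mx, my) {
  checkComparable(mx, my)
  if (!length(mx@words) || !length(my@words))
    stop("total variation distance is undefined for an empty word set")
  p <- lengthDistribution(mx@words)
  q <- lengthDistribution(my@words)
  lens <- union(names(p), names(q))
  pv <- ifelse(lens %in% names(p), p[lens], 0)
  qv <- ifelse(lens %in% names(q), q[lens], 0)
  sum(abs(pv - qv)) / 2
}

# Normalized word-length histogram (names = lengths, values sum to 1).
lengthDistribution <- function(w) {
  h <- table(nchar(w))
  v <- as.numeric(h) / length(w)
  names(v) <- names(h)
  v
}

gcFraction <- function(w) {
  tot <- sum(nchar(w))
  if (tot == 0L) return(NA_real_)
  sum(nchar(gsub("[^GC]", "", w))) / tot
}

checkDna <- function(ws) {
  if (!isDnaAlphabet(ws@alphabet))
    stop("GC-content indexes require the DNA alphabet")
  invisible(TRUE)
}

#' GC content of the symmetric difference
#'
#' Fraction of G plus C characters among all characters of the members of
#' the symmetric difference of the two word sets (characters are pooled
#' across words, not averaged per word). An empty symmetric difference
#' (identical sets) scores 0.
#'
#' @inheritParams lwiSymmetricDifference
#' @return numeric in \[0, 1\].
#' @export
gccSymmetricDifference <- function(mx, my) {
  checkComparable(mx, my)
  checkDna(mx)
  d <- c(setdiff(mx@words, my@words), setdiff(my@words, mx@words))
  if (!length(d)) return(0)
  gcFraction(d)
}

#' One minus the GC content of the intersection
#'
#' The GC fraction of the shared words measures similarity, so the index is
#' its complement. An empty intersection (nothing shared) scores 1.
#'
#' @inheritParams lwiSymmetricDifference
#' @return numeric in \[0, 1\].
#' @export
gccIntersection <- function(mx, my) {
  checkComparable(mx, my)
  checkDna(mx)
  i <- intersect(mx@words, my@words)
  if (!length(i)) return(1)
  1 - gcFraction(i)
}

checkRawPair <- function(ri, rj) {
  stopifnot(is(ri, "WordSet"), is(rj, "WordSet"))
  if (ri@kind != "RAW" || rj@kind != "RAW")
    stop("expected RAW word sets")
  if (!identical(ri@sourceIds, rev(rj@sourceIds)))
    stop("RAW sets must come from the two orderings of the same record pair")
  if (ri@setting != rj@setting)
    stop("RAW sets were computed under different strand settings")
  invisible(TRUE)
}

#' Averaged length-weighted index on relative absent word sets
#'
#' For a pair of sequences, the minimal relative absent words are computed
#' in both directions (each sequence in turn as target, the other as
#' reference); the distance is the average of the two length-weighted
#' indexes, which makes it symmetric.
#'
#' @param ri,rj [WordSet-class] objects of kind `"RAW"` for the ordered
#'   pairs (i, j) and (j, i) of the same two records.
#' @return non-negative numeric; 0 for identical sequences.
#' @examples
#' a <- SegmentedSequence("t", "ACGT"); b <- SegmentedSequence("r", "AAAA")
#' rawLwiDistance(minimalRelativeWords(a, b), minimalRelativeWords(b, a))
#' # 1.625
#' @export
rawLwiDistance <- function(ri, rj) {
  checkRawPair(ri, rj)
  (lwi(ri) + lwi(rj)) / 2
}

#' Averaged GC content on relative absent word sets
#'
#' Average of the GC fractions of the two directed minimal relative absent
#' word sets; an empty set contributes 0.
#'
#' @inheritParams rawLwiDistance
#' @return numeric in \[0, 1\].
#' @export
rawGccDistance <- function(ri, rj) {
  checkRawPair(ri, rj)
  checkDna(ri)
  g <- function(ws) if (!length(ws@words)) 0 else gcFraction(ws@words)
  (g(ri) + g(rj)) / 2
}
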