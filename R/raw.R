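#' The set of k-length factors of a record
#'
#' All distinct length-`k` substrings of any segment; empty when every
#' segment is shorter than `k`. Factors never span segment boundaries.
#'
#' @param x a [SegmentedSequence-class].
#' @param k word length, a positive integer.
#' @return a [WordSet-class] of kind `"KMER"`.
#' @examples
#' words(kmerWords(SegmentedSequence("s", c("AC", "GT")), 2))  # "AC" "GT"
#' @export
kmerWords <- function(x, k) {
  stopifnot(is(x, "SegmentedSequence"), k >= 1)
  new("WordSet", words = sortWords(presentKmers(x@segments, as.integer(k))),
      alphabet = x@alphabet, kind = "KMER", sourceIds = x@id,
      setting = x@setting)
}

#' Relative absent words of fixed length
#'
#' The k-length words present in the target but absent from the reference:
#' the set difference of the two k-mer sets.
#'
#' @param target,reference [SegmentedSequence-class] records over the same
#'   alphabet.
#' @param k word length.
#' @return a [WordSet-class] of kind `"RAW"` with
#'   `sourceIds = c(target, reference)`.
#' @export
relativeWords <- function(target, reference, k) {
  checkSameAlphabet(target, reference)
  w <- setdiff(presentKmers(target@segments, as.integer(k)),
               presentKmers(reference@segments, as.integer(k)))
  new("WordSet", words = sortWords(w), alphabet = target@alphabet,
      kind = "RAW", sourceIds = c(target@id, reference@id),
      setting = target@setting)
}

#' Minimal relative absent words
#'
#' Iterates word lengths k = 1..`kMax`. At each k the relative absent words
#' (present in the target, absent from the reference) are computed, and a
#' word is kept only if it is minimal: it contains no shorter reported
#' minimal word as a factor. A minimal relative absent word of size k
#' therefore never contains one of size less than k. The iteration stops
#' early once the target has no factors of the current length.
#'
#' @param target,reference [SegmentedSequence-class] records over the same
#'   alphabet.
#' @param kMax largest word length considered (default 24; the
#'   length-weighted index decays as 1/k^2, so large k contributes little).
#' @return a [WordSet-class] of kind `"RAW"`, union over k of the minimal
#'   sets, with `sourceIds = c(target, reference)`.
#' @examples
#' a <- SegmentedSequence("t", "ACGT"); b <- SegmentedSequence("r", "AAAA")
#' words(minimalRelativeWords(a, b, 4))  # "C" "G" "T"
#' words(minimalRelativeWords(b, a, 4))  # "AA"
#' @export
minimalRelativeWords <- function(target, reference, kMax = 24) {
  checkSameAlphabet(target, reference)
  stopifnot(kMax >= 1)
  acc <- character()
  for (k in seq_len(kMax)) {
    wt <- presentKmers(target@segments, k)
    if (!length(wt)) break
    rk <- setdiff(wt, presentKmers(reference@segments, k))
    if (length(acc) && length(rk)) {
      minimal <- vapply(rk, function(w)
        !any(vapply(acc, grepl, logical(1), x = w, fixed = TRUE)),
        logical(1), USE.NAMES = FALSE)
      rk <- rk[minimal]
    }
    acc <- c(acc, rk)
  }
  new("WordSet", words = sortWords(acc), alphabet = target@alphabet,
      kind = "RAW", sourceIds = c(target@id, reference@id),
      setting = target@setting)
}

checkSameAlphabet <- function(x, y) {
  stopifnot(is(x, "SegmentedSequence"), is(y, "SegmentedSequence"))
  if (!identical(x@alphabet@symbols, y@alphabet@symbols))
    stop(sprintf("alphabet mismatch between records '%s' and '%s'",
                 x@id, y@id))
  invisible(TRUE)
}
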