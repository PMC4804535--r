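# Distinct k-mers occurring in any segment (factors never span boundaries).
presentKmers <- function(segs, k) {
  hits <- lapply(segs, function(s) {
    L <- nchar(s)
    if (L < k) character() else substring(s, 1:(L - k + 1L), k:L)
  })
  unique(unlist(hits, use.names = FALSE))
}

sortWords <- function(w) sort(unique(w), method = "radix")

#' Enumerate the minimal absent words of a sequence
#'
#' A word is absent from a sequence when it occurs in no segment as a factor
#' (substring); an absent word is a minimal absent word (MAW) when all of its
#' proper factors occur. Equivalently, a word w of length k >= 2 is a MAW iff
#' w is absent while both its length-(k-1) prefix and suffix are present
#' (presence of all shorter factors follows, since the factors of a present
#' word are present); a single symbol is a MAW iff it never occurs. The
#' enumeration builds per-length present-k-mer tables and extends present
#' (k-1)-mers by one symbol, which yields every MAW up to the natural length
#' bound (longest segment + 1) without enumerating the full word space.
#'
#' Words are reported over the full alphabet: a DNA record containing no G
#' yields the single-character MAW "G".
#'
#' @param x a [SegmentedSequence-class].
#' @param maxLen report only MAWs of length at most `maxLen`
#'   (default `Inf`, i.e. the natural bound).
#' @return a [WordSet-class] of kind `"MAW"`, sorted, duplicate-free.
#' @examples
#' ab <- binaryAlphabet()
#' words(enumerateMaws(SegmentedSequence("x", "abbaab", ab)))
#' # "aaa" "aabb" "aba" "bab" "bbb"
#' @seealso [bruteForceMaws()] for the literal-definition test oracle.
#' @export
enumerateMaws <- function(x, maxLen = Inf) {
  stopifnot(is(x, "SegmentedSequence"), maxLen >= 1)
  segs <- x@segments
  sym <- x@alphabet@symbols
  nmax <- max(nchar(segs))
  prev <- presentKmers(segs, 1L)
  maws <- setdiff(sym, prev)
  k <- 2L
  while (k <= maxLen && k <= nmax + 1L && length(prev)) {
    cur <- if (k <= nmax) presentKmers(segs, k) else character()
    cand <- as.vector(outer(prev, sym, paste0))   # prefix present by build
    cand <- cand[!(cand %in% cur)]                # absent
    cand <- cand[substring(cand, 2L, k) %in% prev]  # suffix present
    maws <- c(maws, cand)
    prev <- cur
    k <- k + 1L
  }
  new("WordSet", words = sortWords(maws), alphabet = x@alphabet,
      kind = "MAW", sourceIds = x@id, setting = x@setting)
}

#' Literal brute-force minimal absent words (test oracle)
#'
#' Independent oracle for [enumerateMaws()]: explores the word space in order
#' of length, keeping as the live frontier exactly the words that literally
#' occur in some segment (substring search, no k-mer tables). Every one-symbol
#' extension of a live word that is absent is then tested against the raw
#' definition — every proper factor is extracted and substring-searched. The
#' search is complete: a minimal absent word's length-(k-1) prefix is one of
#' its proper factors and hence present, so every MAW is reached from the live
#' frontier; conversely any word with an absent proper prefix is not minimal,
#' and extensions of absent words contain them as proper factors.
#'
#' @param x a [SegmentedSequence-class].
#' @param maxLen maximum word length to search (finite).
#' @param guard resource guard on the candidate frontier size per length.
#' @return a [WordSet-class] of kind `"MAW"`, identical to
#'   `enumerateMaws(x, maxLen)` restricted to `maxLen`.
#' @export
bruteForceMaws <- function(x, maxLen, guard = 1e7) {
  stopifnot(is(x, "SegmentedSequence"), is.finite(maxLen), maxLen >= 1)
  segs <- x@segments
  sym <- x@alphabet@symbols
  isFactor <- function(w)
    any(vapply(segs, function(s) grepl(w, s, fixed = TRUE), logical(1)))
  allProperFactorsPresent <- function(w) {
    k <- nchar(w)
    if (k == 1L) return(TRUE)  # only the empty word, trivially present
    for (len in 1:(k - 1L))
      for (i in 1:(k - len + 1L))
        if (!isFactor(substr(w, i, i + len - 1L))) return(FALSE)
    TRUE
  }
  maws <- character()
  alive <- ""                      # empty word, factor of everything
  k <- 1L
  while (k <= maxLen && length(alive)) {
    cand <- as.vector(outer(alive, sym, paste0))
    if (length(cand) > guard)
      stop(sprintf("brute-force frontier exceeds guard (%g candidates)",
                   length(cand)))
    present <- vapply(cand, isFactor, logical(1), USE.NAMES = FALSE)
    absent <- cand[!present]
    maws <- c(maws, absent[vapply(absent, allProperFactorsPresent,
                                  logical(1), USE.NAMES = FALSE)])
    alive <- cand[present]
    k <- k + 1L
  }
  new("WordSet", words = sortWords(maws), alphabet = x@alphabet,
      kind = "MAW", sourceIds = x@id, setting = x@setting)
}

#' Write a word set as plain text
#'
#' One word per line in lexicographic order (the output style of common
#' absent-word enumeration tools).
#'
#' @param ws a [WordSet-class].
#' @param path output file path.
#' @export
writeWordSet <- function(ws, path) {
  stopifnot(is(ws, "WordSet"))
  writeLines(ws@words, path)
  invisible(path)
}
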