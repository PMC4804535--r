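#' Random sequence records for simulation and testing
#'
#' Generates uniform i.i.d. random sequences over an alphabet, as
#' [SegmentedSequence-class] records. Uniform random strings are the
#' appropriate null model for exercising the absent-word machinery: short
#' random sequences have rich, irregular minimal-absent-word structure
#' while remaining cheap to verify against the literal-definition oracle.
#' Randomness comes from R's global RNG — call `set.seed()` first for
#' reproducibility; the package itself never seeds.
#'
#' @param n how many records.
#' @param minLen,maxLen record length is drawn uniformly from
#'   `minLen:maxLen`.
#' @param alphabet an [Alphabet-class]; default DNA.
#' @param idPrefix record ids are `paste0(idPrefix, seq_len(n))`.
#' @return list of [SegmentedSequence-class] records (single segment,
#'   setting `"noRC"`).
#' @examples
#' set.seed(1)
#' randomRecords(2, 5, 10)
#' @export
randomRecords <- function(n, minLen, maxLen = minLen,
                          alphabet = dnaAlphabet(), idPrefix = "seq") {
  stopifnot(n >= 1, minLen >= 1, maxLen >= minLen)
  lens <- sample(minLen:maxLen, n, replace = TRUE)
  lapply(seq_len(n), function(i) {
    s <- paste(sample(alphabet@symbols, lens[i], replace = TRUE),
               collapse = "")
    SegmentedSequence(paste0(idPrefix, i), s, alphabet)
  })
}

#' @rdname randomRecords
#' @param len string length.
#' @return `randomString`: a single character string.
#' @export
randomString <- function(len, alphabet = dnaAlphabet()) {
  paste(sample(alphabet@symbols, len, replace = TRUE), collapse = "")
}
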