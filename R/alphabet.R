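#' Standard alphabets
#'
#' `dnaAlphabet()` is the four-letter DNA alphabet with the Watson-Crick
#' complement map; `binaryAlphabet()` is the two-letter alphabet \{a, b\}
#' used for small worked examples (no complement map, so reverse-complement
#' and GC-content operations are not available on it).
#'
#' @return an [Alphabet-class] object.
#' @examples
#' dnaAlphabet()
#' @export
dnaAlphabet <- function() {
  new("Alphabet", symbols = c("A", "C", "G", "T"),
      complement = c(A = "T", C = "G", G = "C", T = "A"))
}

#' @rdname dnaAlphabet
#' @export
binaryAlphabet <- function() {
  new("Alphabet", symbols = c("a", "b"), complement = character())
}

#' @rdname dnaAlphabet
#' @param symbols character vector of distinct single-character symbols.
#' @param complement optional named character vector (a self-inverse
#'   bijection on `symbols`).
#' @export
Alphabet <- function(symbols, complement = character()) {
  new("Alphabet", symbols = symbols, complement = complement)
}

hasComplement <- function(alphabet) length(alphabet@complement) > 0L

isDnaAlphabet <- function(alphabet) {
  setequal(alphabet@symbols, c("A", "C", "G", "T")) && hasComplement(alphabet)
}

#' @describeIn reverseComplement on a character vector of sequences.
#' @param alphabet an [Alphabet-class] with a complement map.
setMethod("reverseComplement", "character",
          function(x, alphabet = dnaAlphabet()) {
  if (!hasComplement(alphabet))
    stop("reverse complement is undefined: alphabet has no complement map")
  cm <- alphabet@complement
  vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(ch, names(cm))
    if (length(bad))
      stop(sprintf("characters outside alphabet: %s",
                   paste(unique(bad), collapse = ", ")))
    paste(rev(unname(cm[ch])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
})

#' @describeIn reverseComplement on a [SegmentedSequence-class]: each segment
#'   is reverse-complemented and the segment order reversed, so the result is
#'   the reverse complement of the (sentinel-separated) record.
setMethod("reverseComplement", "SegmentedSequence", function(x) {
  new("SegmentedSequence", id = x@id,
      segments = rev(reverseComplement(x@segments, x@alphabet)),
      alphabet = x@alphabet, setting = x@setting)
})
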