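#' @rdname WordSet-class
#' @param x a package object.
#' @export
setGeneric("words", function(x) standardGeneric("words"))

#' @rdname WordSet-class
#' @export
setGeneric("wordKind", function(x) standardGeneric("wordKind"))

#' @rdname WordSet-class
#' @export
setGeneric("sourceIds", function(x) standardGeneric("sourceIds"))

#' @rdname SegmentedSequence-class
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname SegmentedSequence-class
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))

#' Strand setting of an object
#' @param x a [SegmentedSequence-class], [WordSet-class] or
#'   [WordDistanceMatrix-class].
#' @return `"noRC"` or `"RC"`.
#' @export
setGeneric("setting", function(x) standardGeneric("setting"))

#' Alphabet of an object
#' @param x a package object carrying an [Alphabet-class].
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))

#' @rdname WordDistanceMatrix-class
#' @param x a [WordDistanceMatrix-class].
#' @export
setGeneric("distValues", function(x) standardGeneric("distValues"))

#' @rdname WordDistanceMatrix-class
#' @export
setGeneric("measure", function(x) standardGeneric("measure"))

#' Reverse complement of a sequence
#'
#' Reverses the symbol-wise complement of its argument. Defined for plain
#' character vectors of sequences (given an alphabet with a complement map)
#' and for [SegmentedSequence-class] objects (per segment, preserving the
#' record's segmentation).
#'
#' @param x character vector of sequences, or a [SegmentedSequence-class].
#' @param ... further arguments; for the character method, `alphabet`
#'   (default [dnaAlphabet()]).
#' @return an object of the same shape as `x`.
#' @examples
#' reverseComplement("AAC")   # "GTT"
#' @export
setGeneric("reverseComplement",
           function(x, ...) standardGeneric("reverseComplement"))
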