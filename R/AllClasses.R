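#' @import methods
NULL

MEASURES <- c("LWI_SYM", "LWI_INT", "JACCARD", "TVD",
              "GCC_SYM", "GCC_INT", "RAW_LWI", "RAW_GCC")
SETTINGS <- c("noRC", "RC")
WORD_KINDS <- c("MAW", "RAW", "KMER")

#' Alphabet for sequence analysis
#'
#' A finite, ordered set of single-character symbols, optionally equipped with
#' a complement map (an involution on the symbols, e.g. A<->T, C<->G for DNA).
#' Operations that need complementation (reverse complement, the RC setting)
#' or base composition (GC content) require a suitable alphabet; set-theoretic
#' word operations work over any alphabet.
#'
#' @slot symbols character vector of distinct single characters.
#' @slot complement named character vector mapping each symbol to its
#'   complement, or empty when the alphabet has no complement structure.
#'
#' @seealso [dnaAlphabet()], [binaryAlphabet()]
#' @exportClass Alphabet
setClass("Alphabet",
         slots = c(symbols = "character", complement = "character"))

setValidity("Alphabet", function(object) {
  s <- object@symbols
  if (length(s) < 1L) return("alphabet must contain at least one symbol")
  if (anyDuplicated(s)) return("alphabet symbols must be distinct")
  if (any(nchar(s) != 1L)) return("alphabet symbols must be single characters")
  cm <- object@complement
  if (length(cm)) {
    if (!setequal(names(cm), s) || !all(cm %in% s))
      return("complement map must be a bijection on the alphabet symbols")
    if (!identical(unname(cm[cm]), names(cm)))
      return("complement map must be self-inverse")
  }
  TRUE
})

#' A segmented, single-stranded sequence record
#'
#' A named sequence over an [Alphabet-class], stored as an ordered list of
#' segments. Factors (substrings) never span a segment boundary, so segments
#' model sentinel-separated pieces: runs of ambiguous bases split a record
#' into segments, and the reverse-complement (RC) setting appends the reverse
#' complements of the segments as additional segments, so that no artificial
#' word across the forward/reverse junction is ever counted.
#'
#' @slot id non-empty record label.
#' @slot segments character vector of non-empty strings over the alphabet.
#' @slot alphabet the [Alphabet-class] the segments are written in.
#' @slot setting `"noRC"` for a plain record, `"RC"` for a record already
#'   augmented with its reverse complement (see [makeRCSetting()]).
#'
#' @seealso [SegmentedSequence()], [readFastaRecords()], [makeRCSetting()]
#' @exportClass SegmentedSequence
setClass("SegmentedSequence",
         slots = c(id = "character", segments = "character",
                   alphabet = "Alphabet", setting = "character"))

setValidity("SegmentedSequence", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id))
    return("id must be a single non-empty string")
  if (length(object@segments) < 1L || any(!nzchar(object@segments)))
    return("segments must be a non-empty list of non-empty strings")
  if (length(object@setting) != 1L || !object@setting %in% SETTINGS)
    return("setting must be 'noRC' or 'RC'")
  sym <- object@alphabet@symbols
  chars <- unique(strsplit(paste(object@segments, collapse = ""), "")[[1]])
  bad <- setdiff(chars, sym)
  if (length(bad))
    return(sprintf("characters outside alphabet in record '%s': %s",
                   object@id, paste(bad, collapse = ", ")))
  TRUE
})

#' A finite set of words over an alphabet
#'
#' Container for the word sets the package computes: minimal absent words
#' (kind `"MAW"`), minimal relative absent words (kind `"RAW"`, with an
#' ordered (target, reference) pair of source ids), and plain k-mer sets
#' (kind `"KMER"`). Words are stored sorted and duplicate-free.
#'
#' @slot words character vector of distinct non-empty words.
#' @slot alphabet the [Alphabet-class] the words are written in.
#' @slot kind one of `"MAW"`, `"RAW"`, `"KMER"`.
#' @slot sourceIds label of the source record (MAW/KMER) or the ordered
#'   (target, reference) pair (RAW).
#' @slot setting strand setting the source record(s) were in.
#'
#' @seealso [enumerateMaws()], [minimalRelativeWords()], [kmerWords()]
#' @exportClass WordSet
setClass("WordSet",
         slots = c(words = "character", alphabet = "Alphabet",
                   kind = "character", sourceIds = "character",
                   setting = "character"))

setValidity("WordSet", function(object) {
  if (length(object@kind) != 1L || !object@kind %in% WORD_KINDS)
    return("kind must be one of MAW, RAW, KMER")
  if (anyDuplicated(object@words)) return("words must be distinct")
  if (length(object@words) && any(!nzchar(object@words)))
    return("words must be non-empty")
  if (object@kind == "RAW" && length(object@sourceIds) != 2L)
    return("RAW word sets need an ordered (target, reference) id pair")
  if (object@kind != "RAW" && length(object@sourceIds) != 1L)
    return("MAW/KMER word sets need exactly one source id")
  if (length(object@setting) != 1L || !object@setting %in% SETTINGS)
    return("setting must be 'noRC' or 'RC'")
  TRUE
})

#' Labeled pairwise distance matrix over a set of sequences
#'
#' Symmetric matrix of pairwise index values with a zero diagonal, tagged
#' with the measure and strand setting it was computed under. Off-diagonal
#' values may be negative for the intersection length-weighted index; tree
#' reconstruction applies a documented shift in that case.
#'
#' @slot values symmetric numeric matrix with identical, unique row/column
#'   labels and zero diagonal.
#' @slot measure one of the eight supported measure codes.
#' @slot setting `"noRC"` or `"RC"`.
#'
#' @seealso [buildDistanceMatrix()], [rankedNeighbors()], [upgmaTree()]
#' @exportClass WordDistanceMatrix
setClass("WordDistanceMatrix",
         slots = c(values = "matrix", measure = "character",
                   setting = "character"))

setValidity("WordDistanceMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v) || nrow(v) != ncol(v))
    return("values must be a square numeric matrix")
  lab <- rownames(v)
  if (is.null(lab) || is.null(colnames(v)) || !identical(lab, colnames(v)))
    return("values must have identical row and column labels")
  if (anyDuplicated(lab)) return("labels must be unique")
  if (any(!is.finite(v))) return("values must be finite")
  if (any(abs(v - t(v)) > 1e-12)) return("values must be symmetric")
  if (any(diag(v) != 0)) return("diagonal must be zero")
  if (length(object@measure) != 1L || !object@measure %in% MEASURES)
    return(sprintf("measure must be one of: %s",
                   paste(MEASURES, collapse = ", ")))
  if (length(object@setting) != 1L || !object@setting %in% SETTINGS)
    return("setting must be 'noRC' or 'RC'")
  TRUE
})

#' Report on the six expected biological relations
#'
#' Result of [evaluateRelations()]: for each of the six expected relations
#' among the 11 beta-globin benchmark species (REL1..REL6), whether the
#' distance matrix satisfies it, plus human-readable evidence.
#'
#' @slot satisfied named logical vector, one entry per relation REL1..REL6.
#' @slot details named character vector of evidence strings.
#'
#' @exportClass RelationReport
setClass("RelationReport",
         slots = c(satisfied = "logical", details = "character"))

setValidity("RelationReport", function(object) {
  ids <- paste0("REL", 1:6)
  if (!identical(names(object@satisfied), ids))
    return("satisfied must be named REL1..REL6")
  if (!identical(names(object@details), ids))
    return("details must be named REL1..REL6")
  TRUE
})
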