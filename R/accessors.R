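#' @describeIn WordSet-class the sorted word vector.
setMethod("words", "WordSet", function(x) x@words)

#' @describeIn WordSet-class the set kind (`"MAW"`, `"RAW"` or `"KMER"`).
setMethod("wordKind", "WordSet", function(x) x@kind)

#' @describeIn WordSet-class source record id(s).
setMethod("sourceIds", "WordSet", function(x) x@sourceIds)

#' @describeIn SegmentedSequence-class the segment strings.
setMethod("segments", "SegmentedSequence", function(x) x@segments)

#' @describeIn SegmentedSequence-class the record label.
setMethod("seqId", "SegmentedSequence", function(x) x@id)

setMethod("setting", "SegmentedSequence", function(x) x@setting)
setMethod("setting", "WordSet", function(x) x@setting)
setMethod("setting", "WordDistanceMatrix", function(x) x@setting)

setMethod("alphabet", "SegmentedSequence", function(x) x@alphabet)
setMethod("alphabet", "WordSet", function(x) x@alphabet)

#' @describeIn WordDistanceMatrix-class the symmetric value matrix.
setMethod("distValues", "WordDistanceMatrix", function(x) x@values)

#' @describeIn WordDistanceMatrix-class the measure code.
setMethod("measure", "WordDistanceMatrix", function(x) x@measure)

#' @describeIn WordDistanceMatrix-class the species labels.
#' @param object a package object (for `labels` and `show`).
#' @param ... unused.
#' @export
setMethod("labels", "WordDistanceMatrix",
          function(object, ...) rownames(object@values))

#' @describeIn RelationReport-class named logical vector of verdicts.
#' @param x a [RelationReport-class].
#' @export
satisfied <- function(x) {
  stopifnot(is(x, "RelationReport"))
  x@satisfied
}

#' @describeIn RelationReport-class named character vector of evidence.
#' @export
relationDetails <- function(x) {
  stopifnot(is(x, "RelationReport"))
  x@details
}

setMethod("show", "Alphabet", function(object) {
  cat("Alphabet of", length(object@symbols), "symbols:",
      paste(object@symbols, collapse = " "), "\n")
  if (length(object@complement))
    cat("  complement:",
        paste(names(object@complement), object@complement,
              sep = "->", collapse = " "), "\n")
})

setMethod("show", "SegmentedSequence", function(object) {
  n <- sum(nchar(object@segments))
  cat(sprintf("SegmentedSequence '%s' (%s): %d segment(s), %d residues\n",
              object@id, object@setting, length(object@segments), n))
})

setMethod("show", "WordSet", function(object) {
  cat(sprintf("WordSet (%s, %s) from %s: %d word(s)\n",
              object@kind, object@setting,
              paste(object@sourceIds, collapse = " | "),
              length(object@words)))
  if (length(object@words)) {
    h <- table(nchar(object@words))
    cat("  lengths:",
        paste(sprintf("%s:%d", names(h), as.integer(h)), collapse = " "), "\n")
  }
})

setMethod("show", "WordDistanceMatrix", function(object) {
  cat(sprintf("WordDistanceMatrix: %s (%s setting), %d taxa\n",
              object@measure, object@setting, nrow(object@values)))
  print(round(object@values, 2))  # display convention; stored values are exact
})

setMethod("show", "RelationReport", function(object) {
  cat("RelationReport:", sum(object@satisfied), "of 6 relations satisfied\n")
  for (id in names(object@satisfied))
    cat(sprintf("  %s [%s] %s\n", id,
                if (object@satisfied[[id]]) "ok" else "FAIL",
                object@details[[id]]))
})
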