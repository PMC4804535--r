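#' Construct a segmented sequence record
#'
#' @param id non-empty record label.
#' @param segments character vector of non-empty segment strings; factors
#'   never span segment boundaries.
#' @param alphabet an [Alphabet-class]; default DNA.
#' @param setting `"noRC"` (default) or `"RC"`.
#' @return a [SegmentedSequence-class].
#' @examples
#' SegmentedSequence("toy", "ACGT")
#' @export
SegmentedSequence <- function(id, segments, alphabet = dnaAlphabet(),
                              setting = "noRC") {
  new("SegmentedSequence", id = id, segments = segments,
      alphabet = alphabet, setting = setting)
}

#' Read DNA records from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file into
#' [SegmentedSequence-class] records. Input is uppercased (soft-masked FASTA
#' is common). Characters outside the alphabet — ambiguity codes such as N —
#' are handled by `ambiguityPolicy`: under `"split"` each maximal run of
#' non-alphabet characters becomes a segment boundary (absent-word logic is
#' undefined across degenerate symbols); under `"reject"` any non-alphabet
#' character is an error naming the record and position.
#'
#' @param path FASTA file path.
#' @param alphabet target [Alphabet-class]; default DNA.
#' @param ambiguityPolicy `"split"` (default) or `"reject"`.
#' @return list of [SegmentedSequence-class], setting `"noRC"`, one per
#'   FASTA record, named by record id.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "acgNNtt"), fa)
#' segments(readFastaRecords(fa)[["s1"]])  # "ACG" "TT"
#' @export
readFastaRecords <- function(path, alphabet = dnaAlphabet(),
                             ambiguityPolicy = c("split", "reject")) {
  ambiguityPolicy <- match.arg(ambiguityPolicy)
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop(sprintf("no FASTA records in %s", path))
  # record id = first whitespace-delimited token of the header
  ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[`, character(1), 1L)
  if (any(is.na(ids)) || any(!nzchar(ids)))
    stop(sprintf("FASTA record with empty id in %s", path))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate FASTA record id(s): %s", paste(dup, collapse = ", ")))
  raw <- toupper(as.character(seqs))
  sym <- alphabet@symbols
  recs <- lapply(seq_along(raw), function(i) {
    s <- raw[[i]]
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    ok <- chars %in% sym
    if (ambiguityPolicy == "reject" && !all(ok))
      stop(sprintf("non-alphabet character '%s' at position %d of record '%s'",
                   chars[which(!ok)[1]], which(!ok)[1], ids[[i]]))
    segs <- strsplit(gsub(sprintf("[^%s]+", paste(sym, collapse = "")), "\n", s),
                     "\n", fixed = TRUE)[[1]]
    segs <- segs[nzchar(segs)]
    if (!length(segs))
      stop(sprintf("record '%s' has no usable residues", ids[[i]]))
    SegmentedSequence(ids[[i]], segs, alphabet)
  })
  names(recs) <- ids
  recs
}

#' Augment a record with its reverse complement (RC setting)
#'
#' Returns a record whose segments are the original segments followed by the
#' reverse complements of the segments in reverse order — i.e. the sequence
#' concatenated with its reverse complement, with the junction treated as a
#' segment boundary. Because factors never span segment boundaries, no
#' artificial word across the forward/reverse junction is counted.
#'
#' @param x a [SegmentedSequence-class] with setting `"noRC"`.
#' @return a [SegmentedSequence-class] with setting `"RC"` and twice the
#'   residue count of `x`.
#' @examples
#' segments(makeRCSetting(SegmentedSequence("s", c("AC", "GG"))))
#' # "AC" "GG" "CC" "GT"
#' @export
makeRCSetting <- function(x) {
  stopifnot(is(x, "SegmentedSequence"))
  if (x@setting != "noRC")
    stop(sprintf("record '%s' is already in the RC setting", x@id))
  rcseg <- rev(reverseComplement(x@segments, x@alphabet))
  new("SegmentedSequence", id = x@id, segments = c(x@segments, rcseg),
      alphabet = x@alphabet, setting = "RC")
}

# Apply the requested strand setting to a list of noRC records.
applySetting <- function(records, setting) {
  if (setting == "noRC") return(records)
  lapply(records, makeRCSetting)
}
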