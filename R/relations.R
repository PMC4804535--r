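# The 11 benchmark species and the six expected biological relations.
#
# The relations are qualitative statements about the beta-globin benchmark
# (primate clustering, ruminant and murid pairs, remoteness of the only
# non-mammal and of the marsupial, relative remoteness of the prosimian);
# the operational criteria below are the weakest quantitative readings that
# are checkable on a distance matrix: nearest-neighbor membership for REL1-3,
# top-k exclusion for REL4-5, and a mean-rank threshold for REL6.

BENCHMARK_SPECIES <- c("human", "goat", "opossum", "gallus", "lemur",
                       "mouse", "rabbit", "rat", "gorilla", "bovine", "chimp")

# Map matrix labels to canonical species keys (case-insensitive; accepts
# "chimpanzee" for chimp). Returns named character: canonical -> label.
canonicalSpeciesMap <- function(lab) {
  low <- tolower(lab)
  low[low == "chimpanzee"] <- "chimp"
  found <- match(BENCHMARK_SPECIES, low)
  missing <- BENCHMARK_SPECIES[is.na(found)]
  if (length(missing))
    stop(sprintf("matrix labels are missing benchmark species: %s",
                 paste(missing, collapse = ", ")))
  stats::setNames(lab[found], BENCHMARK_SPECIES)
}

#' Evaluate the six expected biological relations on a distance matrix
#'
#' Checks, on a matrix over the 11 beta-globin benchmark species
#' (case-insensitive labels; "Chimpanzee" is accepted for "Chimp"):
#' \describe{
#'   \item{REL1}{Gorilla and Chimp are Human's two nearest neighbors
#'     (either order).}
#'   \item{REL2}{Goat and Bovine are mutual nearest neighbors.}
#'   \item{REL3}{Mouse is Rat's nearest neighbor.}
#'   \item{REL4}{Gallus (the only non-mammal) is not among the `topK`
#'     nearest neighbors of any mammal.}
#'   \item{REL5}{Opossum (the marsupial) is not among the `topK` nearest
#'     neighbors of any other species.}
#'   \item{REL6}{Lemur's mean rank across the other species' neighbor
#'     rankings is in the bottom half (mean position > (n-1)/2).}
#' }
#'
#' @param m a [WordDistanceMatrix-class] whose labels include the 11
#'   benchmark species.
#' @param topK neighborhood size for the remoteness checks REL4/REL5
#'   (default 3).
#' @return a [RelationReport-class].
#' @examples
#' evaluateRelations(benchmarkMatrix("RAW_LWI"))
#' @export
evaluateRelations <- function(m, topK = 3) {
  stopifnot(is(m, "WordDistanceMatrix"))
  sp <- canonicalSpeciesMap(labels(m))
  rk <- rankedNeighbors(m)
  pos <- function(focal, other) match(sp[[other]], rk[[sp[[focal]]]])
  nearest <- function(focal, k = 1) rk[[sp[[focal]]]][seq_len(k)]

  sat <- logical(6)
  det <- character(6)

  top2 <- nearest("human", 2)
  sat[1] <- setequal(top2, sp[c("gorilla", "chimp")])
  det[1] <- sprintf("Human's two nearest: %s", paste(top2, collapse = ", "))

  sat[2] <- identical(nearest("goat"), sp[["bovine"]]) &&
            identical(nearest("bovine"), sp[["goat"]])
  det[2] <- sprintf("Goat's nearest: %s; Bovine's nearest: %s",
                    nearest("goat"), nearest("bovine"))

  sat[3] <- identical(nearest("rat"), sp[["mouse"]])
  det[3] <- sprintf("Rat's nearest: %s", nearest("rat"))

  mammals <- setdiff(BENCHMARK_SPECIES, "gallus")
  hitsG <- mammals[vapply(mammals, function(f)
    sp[["gallus"]] %in% nearest(f, topK), logical(1))]
  sat[4] <- length(hitsG) == 0L
  det[4] <- if (sat[4])
    sprintf("Gallus in no mammal's top %d", topK)
  else sprintf("Gallus in top %d of: %s", topK,
               paste(sp[hitsG], collapse = ", "))

  othersO <- setdiff(BENCHMARK_SPECIES, "opossum")
  hitsO <- othersO[vapply(othersO, function(f)
    sp[["opossum"]] %in% nearest(f, topK), logical(1))]
  sat[5] <- length(hitsO) == 0L
  det[5] <- if (sat[5])
    sprintf("Opossum in no other species' top %d", topK)
  else sprintf("Opossum in top %d of: %s", topK,
               paste(sp[hitsO], collapse = ", "))

  othersL <- setdiff(BENCHMARK_SPECIES, "lemur")
  ranksL <- vapply(othersL, function(f) pos(f, "lemur"), numeric(1))
  half <- (length(labels(m)) - 1) / 2
  sat[6] <- mean(ranksL) > half
  det[6] <- sprintf("Lemur's mean neighbor rank %.2f (threshold > %.1f)",
                    mean(ranksL), half)

  ids <- paste0("REL", 1:6)
  new("RelationReport",
      satisfied = stats::setNames(sat, ids),
      details = stats::setNames(det, ids))
}
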