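# Distance-based tree reconstruction. UPGMA and neighbor joining are the
# standard agglomerative methods; they assume non-negative dissimilarities,
# while the intersection length-weighted index is non-positive by design.
# Matrices with negative off-diagonal entries are therefore shifted by
# subtracting the global off-diagonal minimum before agglomeration (diagonal
# stays 0); the applied shift is recorded on the returned tree.

shiftedDist <- function(m) {
  v <- m@values
  off <- v[upper.tri(v)]
  shift <- if (length(off) && min(off) < 0) min(off) else 0
  if (shift < 0) {
    v[upper.tri(v)] <- v[upper.tri(v)] - shift
    v[lower.tri(v)] <- t(v)[lower.tri(v)]
  }
  list(d = stats::as.dist(v), shift = shift)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration producing a rooted ultrametric tree. On an
#' exactly ultrametric input the cophenetic distances of the output equal
#' the input. Negative off-diagonal entries are first removed by a global
#' shift (recorded in the `"shift"` attribute of the result).
#'
#' @param m a [WordDistanceMatrix-class].
#' @return an [ape][ape::read.tree] `phylo` object (rooted), with
#'   attribute `"shift"`.
#' @export
upgmaTree <- function(m) {
  stopifnot(is(m, "WordDistanceMatrix"))
  s <- shiftedDist(m)
  hc <- stats::hclust(s$d, method = "average")
  tr <- ape::as.phylo(hc)
  attr(tr, "shift") <- s$shift
  tr
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration (Q-criterion), producing an unrooted
#' tree; exact on additive matrices. Negative estimated branch lengths are
#' clamped to 0 (the pre-clamp lengths are kept in the
#' `"preClampEdgeLength"` attribute); negative input entries are first
#' removed by a global shift as for [upgmaTree()].
#'
#' @param m a [WordDistanceMatrix-class].
#' @return an [ape][ape::read.tree] `phylo` object (unrooted), with
#'   attributes `"shift"` and `"preClampEdgeLength"`.
#' @export
njTree <- function(m) {
  stopifnot(is(m, "WordDistanceMatrix"))
  s <- shiftedDist(m)
  tr <- ape::nj(s$d)
  pre <- tr$edge.length
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "shift") <- s$shift
  attr(tr, "preClampEdgeLength") <- pre
  tr
}

#' Serialize a tree to Newick
#'
#' Standard Newick with branch lengths at the requested number of
#' significant digits and a terminating semicolon; unrooted trees are
#' written with their (arbitrary) basal multifurcation as stored.
#'
#' @param tree a `phylo` object.
#' @param precision significant digits for branch lengths (default 10).
#' @param path optional file path; when given the string is also written
#'   there.
#' @return the Newick string, invisibly when `path` is given.
#' @export
toNewick <- function(tree, precision = 10, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = precision)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
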