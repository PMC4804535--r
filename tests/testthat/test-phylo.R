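labeledMatrix <- function(v, lab) {
  dimnames(v) <- list(lab, lab)
  WordDistanceMatrix(v, "LWI_SYM")
}

test_that("UPGMA closed forms: two and three taxa", {
  two <- labeledMatrix(matrix(c(0, 2, 2, 0), 2), c("A", "B"))
  tr <- upgmaTree(two)
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 1))
  expect_identical(toNewick(tr), "(A:1,B:1);")

  three <- labeledMatrix(matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3),
                         c("A", "B", "C"))
  tr3 <- upgmaTree(three)
  cop <- ape::cophenetic.phylo(tr3)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(cop, distValues(three))   # ((A:1,B:1):1,C:2)
})

test_that("UPGMA recovers ultrametric matrices exactly", {
  set.seed(606)
  for (i in 1:15) {
    n <- sample(4:12, 1)
    true <- ape::rcoal(n)
    d <- ape::cophenetic.phylo(true)
    m <- labeledMatrix(d, rownames(d))
    got <- ape::cophenetic.phylo(upgmaTree(m))[rownames(d), colnames(d)]
    expect_lt(max(abs(got - d)), 1e-9)
  }
})

test_that("NJ closed form on three taxa", {
  v <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3)
  tr <- njTree(labeledMatrix(v, c("A", "B", "C")))
  el <- tr$edge.length[match(1:3, tr$edge[, 2])]
  names(el) <- tr$tip.label
  expect_equal(el[["A"]], 1)  # (dAB + dAC - dBC) / 2
  expect_equal(el[["B"]], 2)
  expect_equal(el[["C"]], 3)
})

test_that("NJ recovers additive matrices exactly", {
  set.seed(707)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    true <- ape::rtree(n)
    d <- ape::cophenetic.phylo(true)
    m <- labeledMatrix(d, rownames(d))
    got <- ape::cophenetic.phylo(njTree(m))[rownames(d), colnames(d)]
    expect_lt(max(abs(got - d)), 1e-9)
  }
})

test_that("label permutation preserves NJ topology", {
  set.seed(808)
  true <- ape::rtree(8)
  d <- ape::cophenetic.phylo(true)
  t1 <- njTree(labeledMatrix(d, rownames(d)))
  perm <- sample(rownames(d))
  t2 <- njTree(labeledMatrix(d[perm, perm], perm))
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
})

test_that("negative-valued matrices are shifted and branch lengths stay non-negative", {
  v <- matrix(c(0, -0.5, -0.1, -0.5, 0, -0.3, -0.1, -0.3, 0), 3)
  m <- labeledMatrix(v, c("A", "B", "C"))
  for (tr in list(upgmaTree(m), njTree(m))) {
    expect_equal(attr(tr, "shift"), -0.5)
    expect_true(all(tr$edge.length >= 0))
  }
  # NJ clamp metadata is retained even when nothing is clamped
  expect_length(attr(njTree(m), "preClampEdgeLength"),
                length(njTree(m)$edge.length))
})

test_that("Newick output round-trips and handles awkward labels", {
  two <- labeledMatrix(matrix(c(0, 2, 2, 0), 2), c("A x", "B"))
  s <- toNewick(upgmaTree(two))
  expect_match(s, ";$")
  reread <- ape::read.tree(text = s)
  expect_setequal(gsub("_", " ", reread$tip.label), c("A x", "B"))
  expect_identical(ape::write.tree(reread), s)
  f <- tempfile(fileext = ".nwk")
  toNewick(upgmaTree(two), path = f)
  expect_identical(readLines(f), s)
})
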