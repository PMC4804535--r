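mawsOf <- function(s, id = s, alph = binaryAlphabet())
  enumerateMaws(SegmentedSequence(id, s, alph))

dnaSet <- function(words, id = "w", setting = "noRC")
  new("WordSet", words = sort(words), alphabet = dnaAlphabet(),
      kind = "MAW", sourceIds = id, setting = setting)

test_that("length-weighted index values", {
  expect_identical(lwi(character()), 0)
  expect_equal(lwi(c("C", "G", "T")), 3)
  expect_equal(lwi(words(mawsOf("abbaab"))), 4 / 9 + 1 / 16)
})

test_that("worked pair 'abbaab' vs 'aab': LWI, Jaccard, TVD", {
  mx <- mawsOf("abbaab"); my <- mawsOf("aab")
  expect_equal(lwiSymmetricDifference(mx, my), 43 / 48)
  expect_equal(jaccardDistance(mx, my), 6 / 7)
  expect_equal(tvdDistance(mx, my), 2 / 3)
  expect_equal(lwiIntersection(mx, mx), -(4 / 9 + 1 / 16))
})

test_that("index conventions on degenerate sets", {
  a <- dnaSet("A"); cg <- dnaSet("CG"); both <- dnaSet(c("A", "CG"))
  empty <- dnaSet(character())
  expect_equal(lwiSymmetricDifference(a, a), 0)
  expect_equal(lwiSymmetricDifference(a, cg), 1.25)   # disjoint union
  expect_equal(lwiIntersection(a, cg), 0)             # disjoint
  expect_equal(lwiIntersection(both, cg), -0.25)
  expect_equal(jaccardDistance(a, a), 0)
  expect_equal(jaccardDistance(a, cg), 1)
  expect_equal(jaccardDistance(empty, empty), 0)
  expect_error(tvdDistance(empty, a), "empty")
  expect_equal(tvdDistance(a, dnaSet("T")), 0)        # same length histogram
  expect_equal(tvdDistance(a, cg), 1)                 # disjoint supports
})

test_that("GC-content indexes count characters across set members", {
  gc <- dnaSet(c("GC", "G")); at <- dnaSet("AT")
  acg <- dnaSet("ACG")
  expect_equal(gccSymmetricDifference(gc, at), 3 / 5)
  expect_equal(gccSymmetricDifference(acg, at), 2 / 5)  # (1G + 1C) / 5
  expect_equal(gccSymmetricDifference(gc, gc), 0)       # empty difference
  expect_equal(gccIntersection(dnaSet("GC"), dnaSet("GC")), 0)
  expect_equal(gccIntersection(at, at), 1)
  expect_equal(gccIntersection(gc, at), 1)              # empty intersection
  bx <- mawsOf("abbaab")
  expect_error(gccSymmetricDifference(bx, bx), "DNA alphabet")
})

test_that("RAW-based averaged indexes", {
  t <- dnaRec("t", "ACGT"); r <- dnaRec("r", "AAAA")
  ri <- minimalRelativeWords(t, r); rj <- minimalRelativeWords(r, t)
  expect_equal(rawLwiDistance(ri, rj), 1.625)
  expect_equal(rawGccDistance(ri, rj), (2 / 3 + 0) / 2)
  expect_equal(rawLwiDistance(minimalRelativeWords(t, t),
                              minimalRelativeWords(t, t)), 0)
  expect_error(rawLwiDistance(ri, ri), "two orderings")
})

test_that("indexes refuse mismatched settings or alphabets", {
  a <- dnaSet("A"); b <- dnaSet("A", setting = "RC")
  expect_error(jaccardDistance(a, b), "settings")
  expect_error(jaccardDistance(a, mawsOf("ab")), "alphabets")
})

test_that("symmetry, identity, bounds and the LWI decomposition hold", {
  set.seed(404)
  for (i in 1:25) {
    pr <- randomRecords(2, 4, 30)
    mx <- enumerateMaws(pr[[1]]); my <- enumerateMaws(pr[[2]])
    for (f in list(lwiSymmetricDifference, lwiIntersection, jaccardDistance,
                   tvdDistance, gccSymmetricDifference, gccIntersection))
      expect_equal(f(mx, my), f(my, mx))
    expect_equal(lwiSymmetricDifference(mx, mx), 0)
    expect_equal(jaccardDistance(mx, mx), 0)
    expect_equal(tvdDistance(mx, mx), 0)
    for (v in c(jaccardDistance(mx, my), tvdDistance(mx, my),
                gccSymmetricDifference(mx, my), gccIntersection(mx, my))) {
      expect_gte(v, 0); expect_lte(v, 1)
    }
    expect_gte(lwiSymmetricDifference(mx, my), 0)
    expect_lte(lwiIntersection(mx, my), 0)
    # lwi(x delta y) = lwi(x) + lwi(y) - 2 lwi(x intersect y)
    expect_equal(lwiSymmetricDifference(mx, my),
                 lwi(mx) + lwi(my) + 2 * lwiIntersection(mx, my))
    # RAW average is symmetric by construction
    ri <- minimalRelativeWords(pr[[1]], pr[[2]])
    rj <- minimalRelativeWords(pr[[2]], pr[[1]])
    expect_equal(rawLwiDistance(ri, rj), rawLwiDistance(rj, ri))
    g <- rawGccDistance(ri, rj)
    expect_gte(g, 0); expect_lte(g, 1)
  }
})
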