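test_that("distance matrices are symmetric with zero diagonal", {
  recs <- list(binRec("x", "abbaab"), binRec("y", "aab"))
  m <- buildDistanceMatrix(recs, "JACCARD")
  expect_equal(distValues(m)["x", "y"], 6 / 7)
  expect_identical(labels(m), c("x", "y"))

  twin <- list(dnaRec("a", "ACGT"), dnaRec("b", "ACGT"))
  expect_equal(unname(distValues(buildDistanceMatrix(twin, "LWI_SYM"))),
               matrix(0, 2, 2))

  set.seed(505)
  recs <- randomRecords(5, 10, 40)
  for (meas in c("LWI_SYM", "LWI_INT", "TVD", "GCC_INT", "RAW_LWI")) {
    v <- distValues(buildDistanceMatrix(recs, meas, "RC"))
    expect_identical(v, t(v))
    expect_identical(unname(diag(v)), rep(0, 5))
  }
  expect_error(buildDistanceMatrix(recs[1], "JACCARD"), "at least two")
  expect_error(buildDistanceMatrix(recs[c(1, 1)], "JACCARD"), "duplicate")
})

test_that("neighbor rankings on the RAW-LWI benchmark match every published row", {
  rk <- rankedNeighbors(benchmarkMatrix("RAW_LWI"))
  expect_identical(rk, rawLwiRankings)
})

test_that("neighbor rankings on the Jaccard benchmark match published rows up to ties", {
  m <- benchmarkMatrix("JACCARD")
  rk <- rankedNeighbors(m)
  for (focal in names(jaccardRankings))
    expect_true(sameUpToTies(m, focal, rk[[focal]], jaccardRankings[[focal]]))
})

test_that("ranking ties break lexicographically and degenerate case works", {
  v <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3,
              dimnames = list(c("C", "B", "A"), c("C", "B", "A")))
  rk <- rankedNeighbors(WordDistanceMatrix(v, "JACCARD"))
  expect_identical(rk$C, c("A", "B"))  # tie at 1 -> lexicographic
  two <- WordDistanceMatrix(matrix(c(0, 3, 3, 0), 2,
                                   dimnames = list(c("p", "q"), c("p", "q"))),
                            "TVD")
  expect_identical(rankedNeighbors(two), list(p = "q", q = "p"))
})

test_that("all six expected relations hold on the RAW-LWI benchmark", {
  rep <- evaluateRelations(benchmarkMatrix("RAW_LWI"))
  expect_identical(unname(satisfied(rep)), rep(TRUE, 6))
  expect_length(relationDetails(rep), 6)
})

test_that("the Jaccard benchmark captures the three core relations", {
  rep <- evaluateRelations(benchmarkMatrix("JACCARD"))
  expect_true(all(satisfied(rep)[c("REL1", "REL2", "REL3")]))
})

test_that("relation evaluation detects violations and missing species", {
  m <- benchmarkMatrix("RAW_LWI")
  v <- distValues(m)
  v["Human", "Rat"] <- v["Rat", "Human"] <- 0.1  # Rat becomes Human's nearest
  broken <- evaluateRelations(WordDistanceMatrix(v, "RAW_LWI", "RC"))
  expect_false(satisfied(broken)[["REL1"]])
  sub <- WordDistanceMatrix(v[1:5, 1:5], "RAW_LWI", "RC")
  expect_error(evaluateRelations(sub), "missing benchmark species")
})

test_that("matrix serialization round-trips and follows the PHYLIP shape", {
  m <- benchmarkMatrix("RAW_LWI")
  f <- tempfile(fileext = ".csv")
  writeDistanceMatrix(m, f, "csv")
  back <- readDistanceMatrixCsv(f, "RAW_LWI", "RC")
  expect_lt(max(abs(distValues(back) - distValues(m))), 1e-12)
  expect_identical(labels(back), labels(m))

  f2 <- tempfile(fileext = ".phy")
  writeDistanceMatrix(m, f2, "phylip")
  lines <- readLines(f2)
  expect_length(lines, 12)          # count line + one row per taxon
  expect_identical(lines[1], "11")

  two <- WordDistanceMatrix(matrix(0, 2, 2,
                                   dimnames = list(c("A", "B"), c("A", "B"))),
                            "JACCARD")
  f3 <- tempfile(fileext = ".phy")
  writeDistanceMatrix(two, f3, "phylip")
  expect_identical(readLines(f3)[1], "2")
})
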