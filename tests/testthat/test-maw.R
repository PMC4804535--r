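test_that("worked example: MAWs of 'abbaab' over {a,b}", {
  ws <- enumerateMaws(binRec("x", "abbaab"))
  expect_identical(words(ws), c("aaa", "aabb", "aba", "bab", "bbb"))
  expect_true(all(c("aaa", "aba", "bbb") %in% words(ws)))
  expect_false("aaab" %in% words(ws))  # absent but not minimal
  expect_identical(wordKind(ws), "MAW")
})

test_that("small exact MAW sets", {
  expect_identical(words(enumerateMaws(binRec("y", "aab"))),
                   c("aaa", "ba", "bb"))
  expect_identical(words(enumerateMaws(binRec("z", "a"))), c("aa", "b"))
  # absent symbols are reported as single-character MAWs
  expect_true(all(c("C", "G") %in% words(enumerateMaws(dnaRec("d", "ATA")))))
  # present symbols never are
  expect_false("a" %in% words(enumerateMaws(binRec("z", "a"))))
})

test_that("brute-force oracle reproduces the worked examples", {
  expect_identical(words(bruteForceMaws(binRec("x", "abbaab"), 7)),
                   c("aaa", "aabb", "aba", "bab", "bbb"))
  expect_identical(words(bruteForceMaws(binRec("y", "aab"), 4)),
                   c("aaa", "ba", "bb"))
})

test_that("enumeration equals the literal oracle on random records", {
  set.seed(101)
  for (i in 1:60) {
    r <- randomRecords(1, 2, 12, idPrefix = paste0("r", i))[[1]]
    expect_identical(words(enumerateMaws(r, maxLen = 13)),
                     words(bruteForceMaws(r, 13)))
  }
  # multi-segment records (RC setting included)
  for (i in 1:20) {
    r <- makeRCSetting(randomRecords(1, 3, 8)[[1]])
    expect_identical(words(enumerateMaws(r, maxLen = 9)),
                     words(bruteForceMaws(r, 9)))
  }
})

test_that("every reported MAW is absent with both maximal factors present", {
  set.seed(202)
  inAny <- function(w, segs)
    any(vapply(segs, function(s) grepl(w, s, fixed = TRUE), logical(1)))
  for (i in 1:25) {
    r <- randomRecords(1, 5, 20)[[1]]
    segs <- segments(r)
    n <- sum(nchar(segs))
    for (w in words(enumerateMaws(r))) {
      expect_false(inAny(w, segs))
      expect_lte(nchar(w), n + 1L)
      if (nchar(w) > 1L) {
        expect_true(inAny(substr(w, 1, nchar(w) - 1L), segs))
        expect_true(inAny(substr(w, 2, nchar(w)), segs))
      }
    }
  }
})

test_that("maxLen truncates and word-set export is lexicographic", {
  r <- binRec("x", "abbaab")
  expect_identical(words(enumerateMaws(r, maxLen = 3)),
                   c("aaa", "aba", "bab", "bbb"))
  f <- tempfile()
  writeWordSet(enumerateMaws(r), f)
  expect_identical(readLines(f), c("aaa", "aabb", "aba", "bab", "bbb"))
})
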