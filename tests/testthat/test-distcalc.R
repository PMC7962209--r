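test_that("Jaccard and containment estimators follow their definitions", {
  a <- makeSketch(c(1, 2, 3))
  b <- makeSketch(c(2, 3, 4))
  expect_equal(jaccardEstimate(a, b), 0.5)       # 2 shared / 4 union
  expect_equal(containmentEstimate(a, b), 2 / 3)
  expect_equal(jaccardEstimate(a, a), 1)
  d <- makeSketch(c(10, 11))
  expect_equal(jaccardEstimate(a, d), 0)
  expect_equal(containmentEstimate(makeSketch(c(1, 2)),
                                   makeSketch(c(1, 2, 3, 4))), 1)
  # fingerprint mismatch and empty-sketch degeneracies
  other <- makeSketch(c(1, 2), fp = testFingerprint(k = 10L))
  expect_error(jaccardEstimate(a, other), "incompatible-sketch")
  e <- makeSketch(numeric())
  expect_error(jaccardEstimate(e, e), "empty")
  expect_error(containmentEstimate(a, e), "empty")
})

test_that("distance conversions evaluate the Mash and Aaf formulas", {
  expect_equal(as.numeric(mashDistance(1, 21)), 0)
  expect_equal(as.numeric(mashDistance(1 / 3, 21)), log(2) / 21)
  expect_equal(as.numeric(aafDistance(1, 16)), 0)
  expect_equal(as.numeric(aafDistance(0.85, 16)), -log(0.85) / 16)
  expect_equal(as.numeric(aafDistance(exp(-16), 16)), 1)

  # zero coefficients saturate at 1.0 with a flag
  m0 <- mashDistance(0, 16)
  expect_equal(as.numeric(m0), 1)
  expect_true(attr(m0, "saturated"))
  a0 <- aafDistance(c(0, 0.5), 16)
  expect_identical(attr(a0, "saturated"), c(TRUE, FALSE))

  # both conversions are decreasing in the coefficient
  j <- seq(0.01, 1, length.out = 50)
  expect_true(all(diff(as.numeric(mashDistance(j, 16))) < 0))
  expect_true(all(diff(as.numeric(aafDistance(j, 16))) < 0))
})

test_that("proportion statistics give binomial SD, clipped CI, P and Q", {
  s <- proportionStat(0.5, 100)
  expect_equal(s$sd, 0.05)
  expect_equal(s$ciLow, 0.5 - 1.96 * 0.05)
  expect_equal(s$ciHigh, 0.5 + 1.96 * 0.05)
  expect_equal(s$pValue, pnorm(10, lower.tail = FALSE))
  expect_false(s$lowCount)

  z <- proportionStat(0, 50)
  expect_equal(z$sd, 0)
  expect_equal(z$pValue, 1)
  expect_true(z$lowCount)

  one <- proportionStat(1, 50)
  expect_equal(one$pValue, 0)
  expect_equal(one$ciHigh, 1)   # clipped

  # Q multiplies by the number of comparisons and clips at 1
  q <- proportionStat(0.2, 25, nQueries = 2, nRefs = 3)
  expect_equal(q$qValueRaw, q$pValue * 6)
  expect_equal(q$qValue, min(1, q$pValue * 6))
  expect_gte(q$qValue, q$pValue)
  expect_error(proportionStat(0.5, 0), "n must be")
})

test_that("all-vs-all emits every pair and matches a per-pair set oracle", {
  pat <- symmetricPattern(5, 2)
  sp <- shuffleSpace(pat, a = 1, seed = 19)
  qry <- sketchDB(lapply(1:3, function(i) {
    sketchSequences(randomSeq(800, i), pat, sp, sampleId = paste0("q", i),
                    format = "seq")
  }))
  ref <- sketchDB(lapply(1:5, function(i) {
    sketchSequences(randomSeq(700, i + 50), pat, sp,
                    sampleId = paste0("r", i), format = "seq")
  }))
  rec <- allVsAll(qry, ref)
  expect_identical(nrow(rec), 15L)
  expect_identical(rec$query, rep(names(qry), each = 5))  # query-major order

  for (i in seq_len(nrow(rec))) {
    A <- sketchCodes(qry[[rec$query[i]]])
    B <- sketchCodes(ref[[rec$reference[i]]])
    expect_identical(rec$shared[i], length(intersect(A, B)))
    expect_identical(rec$union[i], length(union(A, B)))
    expect_equal(rec$jaccard[i], length(intersect(A, B)) / length(union(A, B)))
    expect_equal(rec$containment[i],
                 length(intersect(A, B)) / min(length(A), length(B)))
    expect_identical(rec$union[i], rec$size_a[i] + rec$size_b[i] - rec$shared[i])
    expect_lte(rec$jaccard[i], rec$containment[i])
  }

  # self comparison
  self <- allVsAll(qry[[1]], qry[[1]])
  expect_equal(self$jaccard, 1)
  expect_equal(self$mash_dist, 0)

  # incompatible databases are refused before any output
  sp2 <- shuffleSpace(pat, a = 1, seed = 20)
  qry2 <- sketchDB(sketchSequences(randomSeq(500, 3), pat, sp2, format = "seq"))
  expect_error(allVsAll(qry2, ref), "incompatible-sketch")

  # TSV round trip
  path <- tempfile(fileext = ".tsv")
  writeDistances(rec, path)
  tab <- read.delim(path)
  expect_identical(nrow(tab), 15L)
  expect_equal(tab$jaccard, signif(rec$jaccard, 6))
})

test_that("with no reduction the estimate equals the exact Jaccard", {
  pat <- symmetricPattern(5, 3)
  sp0 <- shuffleSpace(pat, a = 0, seed = 8)
  s1 <- randomSeq(1200, 61)
  s2 <- randomSeq(1200, 62)
  A <- oracleKmerSet(s1, 10)
  B <- oracleKmerSet(s2, 10)
  skA <- sketchSequences(s1, pat, sp0, format = "seq")
  skB <- sketchSequences(s2, pat, sp0, format = "seq")
  expect_equal(jaccardEstimate(skA, skB),
               length(intersect(A, B)) / length(union(A, B)))
  expect_equal(containmentEstimate(skA, skB),
               length(intersect(A, B)) / min(length(A), length(B)))
})

test_that("the k-length advisor rounds log4(3g/2u) to the nearest even k", {
  expect_identical(suggestK(5e6, 0.001), 16L)
  expect_identical(suggestK(3e9, 0.001), 22L)
  # monotone: fixed g, decreasing u gives non-decreasing k
  ks <- vapply(c(0.01, 0.005, 0.001), function(u) suggestK(1e8, u), 0L)
  expect_true(all(diff(ks) >= 0))
  expect_warning(suggestK(5e6, 0.0001), "outside the recommended range")
})
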