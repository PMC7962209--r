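test_that("symmetric pattern template expands and enforces its constraints", {
  p <- symmetricPattern(6, 1)
  expect_identical(p@pattern, "000001100000")
  expect_identical(p@k, 12L)
  expect_identical(p@w, 2L)
  expect_true(p@symmetric)

  p2 <- symmetricPattern(9, 6)
  expect_identical(p2@pattern, "000111111111111000")
  expect_identical(p2@k, 18L)
  expect_identical(p2@w, 12L)

  expect_error(symmetricPattern(3, 3), "x > y")
  expect_error(symmetricPattern(12, 3), "12 > x")
  expect_error(symmetricPattern(5, 0), "y >= 1")
})

test_that("pattern weight and space dimensionality follow the definitions", {
  expect_identical(patternWeight("000010010000"), 2L)
  expect_identical(patternWeight(strrep("0", 6)), 0L)
  expect_identical(patternWeight(strrep("1", 6)), 6L)
  expect_false(selectionPattern("000010010000")@symmetric)

  expect_equal(spaceDim("000010010000"), 16)
  expect_equal(spaceDim(0), 1)
  expect_equal(spaceDim(6), 4096)
})

test_that("recoding-string length is log4(D/N) = w - a", {
  expect_identical(recodeLength(2, 1), 1L)  # D = 16, N = 4
  expect_identical(recodeLength(5, 5), 0L)
  expect_identical(recodeLength(12, 6), 6L)
  expect_error(recodeLength(2, 3), "a must not exceed w")
})

test_that("the shuffle is a bijection partitioned into equal subspaces", {
  for (w in c(1:6, 8)) {
    sp <- shuffleSpace(w, a = min(w, 2L), seed = w + 10L)
    expect_identical(sort(sp@perm), 0:(4^w - 1L))
  }
  sp <- shuffleSpace(2, a = 1, seed = 3)
  blocks <- table(sp@perm %/% 4L)
  expect_identical(length(blocks), 4L)          # N = 4 subspaces
  expect_true(all(blocks == 4L))                # of 4 dimensions each
  sp2 <- shuffleSpace(2, a = 2, seed = 3)
  expect_true(all(table(sp2@perm %/% 1L) == 1L))  # 16 singleton subspaces
})

test_that("the shuffle is seed-deterministic and seed-sensitive", {
  s1 <- shuffleSpace(6, 2, seed = 7)
  s2 <- shuffleSpace(6, 2, seed = 7)
  expect_identical(s1@perm, s2@perm)
  expect_identical(s1@checksum, s2@checksum)
  for (seed in 1:5) {
    expect_false(identical(shuffleSpace(4, 2, seed = seed)@perm,
                           shuffleSpace(4, 2, seed = seed + 100L)@perm))
  }
})

test_that("subspace membership is uniform across dimensions over seeds", {
  # w = 4, a = 2: each of the 256 dimensions should fall in the chosen
  # subspace with frequency 1/16 over 1,000 seeds (within 3 binomial SE)
  nseeds <- 1000L
  hits <- numeric(256)
  for (seed in seq_len(nseeds)) {
    sp <- shuffleSpace(4, 2, seed = seed)
    hits <- hits + (sp@perm %/% 16L == 0L)
  }
  p <- 1 / 16
  se <- sqrt(p * (1 - p) / nseeds)
  # per-dimension screen at a family-wise bound (256 simultaneous binomial
  # comparisons: a raw 3-SE band is expected to flag ~1 dim by chance)
  bound <- qnorm(1 - 0.01 / (2 * 256))
  expect_true(all(abs(hits / nseeds - p) <= bound * se))
  # and a goodness-of-fit test of global uniformity
  chi <- sum((hits - nseeds * p)^2 / (nseeds * p * (1 - p)))
  expect_gt(pchisq(chi, df = 255, lower.tail = FALSE), 0.001)
})

test_that("shuf files round-trip and refuse corruption", {
  sp <- shuffleSpace(5, 2, seed = 42, chosen = 3)
  path <- tempfile(fileext = ".shuf")
  writeShuf(sp, path)
  back <- readShuf(path)
  expect_identical(back@perm, sp@perm)
  expect_identical(back@w, sp@w)
  expect_identical(back@a, sp@a)
  expect_identical(back@seed, sp@seed)
  expect_identical(back@chosen, sp@chosen)
  expect_identical(back@checksum, sp@checksum)

  bytes <- readBin(path, "raw", file.size(path))
  trunc <- tempfile(fileext = ".shuf")
  writeBin(bytes[1:100], trunc)
  expect_error(readShuf(trunc), "corrupt-file")
  mangled <- bytes
  mangled[60] <- as.raw(bitwXor(as.integer(mangled[60]), 255L))
  bad <- tempfile(fileext = ".shuf")
  writeBin(mangled, bad)
  expect_error(readShuf(bad), "corrupt-file")
  expect_error(readShuf(trunc), "corrupt-file")
})

test_that("a space at reduction level z = 3 reports a 4096-fold reduction", {
  sp <- shuffleSpace(8, a = 6, seed = 1)   # a = 2z with z = 3
  path <- tempfile(fileext = ".shuf")
  writeShuf(sp, path)
  back <- readShuf(path)
  expect_identical(reductionLevel(back), 3L)
  expect_equal(reductionFold(back), 4096)
  expect_equal(reductionFold(3), 4096)
})

test_that("parameter and resource errors are loud", {
  expect_error(shuffleSpace(3, a = 4, seed = 1), "exceeds w")
  expect_error(shuffleSpace(15, a = 2, seed = 1), "resource error")
  expect_error(shuffleSpace(4, a = 2, seed = 1, chosen = 16), "chosen subspace")
})
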