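test_that("canonical k-mers take the lexicographically smaller strand", {
  expect_identical(canonicalKmer("ACGT"), "ACGT")   # palindrome
  expect_identical(canonicalKmer("TT"), "AA")
  expect_identical(canonicalKmer("GAT"), "ATC")
  expect_identical(canonicalKmer("gat"), "ATC")     # case-insensitive
  # agreement with the string oracle across random k-mers
  set.seed(11)
  km <- vapply(1:50, function(i) randomSeq(7, i + 300), "")
  expect_identical(canonicalKmer(km), oracleCanonical(km))
})

test_that("recoding matches hand enumeration on the identity space", {
  # k = 2, p = "01", w = 1, a = 1: subspaces are singletons in lexical
  # order, so subspace 1 holds exactly the dimension 'C'
  sp <- shuffleSpace(1, a = 1, seed = 1, chosen = 1, permute = FALSE)
  expect_equal(recodeKmer("AC", "01", sp), 0)       # p0 = "A" -> 0
  expect_true(is.na(recodeKmer("AA", "01", sp)))    # 'A' not in subspace
  expect_equal(recodeKmer("GC", "01", sp), 2)       # p0 = "G" -> 2
  expect_true(is.na(recodeKmer("AG", "01", sp)))
  expect_error(recodeKmer("ACG", "01", sp), "length")
})

test_that("recoding agrees with the string-level oracle on shuffled spaces", {
  pats <- list(c("0110", 1L), c("010010", 1L), c("011110", 2L))
  for (pc in pats) {
    pat <- pc[1]
    a <- as.integer(pc[2])
    w <- patternWeight(pat)
    k <- nchar(pat)
    sp <- shuffleSpace(w, a = a, seed = 17, chosen = 1L)
    set.seed(5)
    for (i in 1:100) {
      km <- randomSeq(k, i + 1000)
      expect_equal(recodeKmer(km, pat, sp), oracleRecode(km, pat, sp))
    }
  }
})

test_that("recoding is injective: distinct selected k-mers, distinct codes", {
  # enumerate the full k-mer space for small k and w
  for (pc in list(c("0110", 1L), c("110100", 2L), c("101", 1L))) {
    pat <- pc[1]
    a <- as.integer(pc[2])
    k <- nchar(pat)
    sp <- shuffleSpace(patternWeight(pat), a = a, seed = 23)
    all_kmers <- vapply(0:(4^k - 1), int2base4, "", width = k)
    codes <- vapply(all_kmers, function(km) recodeKmer(km, pat, sp),
                    0, USE.NAMES = FALSE)
    sel <- codes[!is.na(codes)]
    expect_false(anyDuplicated(sel) > 0)
    # |r(A)| == |A| restricted to the subspace: selection keeps exactly
    # a 1/N fraction of the dimensionality behind each unselected context
    expect_identical(length(sel), as.integer(4^k / 4^a))
  }
})

test_that("sketching counts windows and matches a brute-force k-mer counter", {
  pat <- symmetricPattern(4, 2)  # k = 8, w = 4
  sp0 <- shuffleSpace(pat, a = 0, seed = 9)
  s <- randomSeq(500, 77)
  sk <- sketchSequences(s, pat, sp0, format = "seq")
  expect_equal(kmerTotal(sk), 500 - 8 + 1)
  # a = 0: every k-mer selected; sketch size equals the distinct canonical
  # k-mer count from an independent set-based scan
  expect_identical(sketchSize(sk), length(oracleKmerSet(s, 8)))
  # non-ACGT characters break windows
  sN <- paste0(substr(s, 1, 100), "N", substr(s, 101, 200))
  skN <- sketchSequences(sN, pat, sp0, format = "seq")
  expect_equal(kmerTotal(skN), (100 - 8 + 1) + (100 - 8 + 1))
})

test_that("occurrence filtering keeps only repeated k-mers", {
  pat <- symmetricPattern(4, 2)
  sp <- shuffleSpace(pat, a = 0, seed = 9)
  # every 8-mer of this sequence is unique -> minOcc = 2 empties the sketch
  s <- "ACGTACGGTTAGCATTAGGCAATC"
  expect_true(length(oracleWindows(s, 8)) ==
                length(unique(oracleCanonical(oracleWindows(s, 8)))))
  expect_warning(sk2 <- sketchSequences(s, pat, sp, minOcc = 2, format = "seq"),
                 "empty sketch")
  expect_identical(sketchSize(sk2), 0L)
  # duplicating the sequence makes every k-mer pass the filter
  sk2b <- sketchSequences(c(s, s), pat, sp, minOcc = 2, format = "seq")
  sk1 <- sketchSequences(s, pat, sp, format = "seq")
  expect_identical(sketchCodes(sk2b), sketchCodes(sk1))
})

test_that("canonical sketches of a sequence and its reverse complement agree", {
  pat <- symmetricPattern(4, 2)
  sp <- shuffleSpace(pat, a = 1, seed = 31)
  s <- randomSeq(2000, 13)
  a <- sketchSequences(s, pat, sp, format = "seq")
  b <- sketchSequences(oracleRevcomp(s), pat, sp, format = "seq")
  expect_identical(sketchCodes(a), sketchCodes(b))
})

test_that("the sketch of concatenated inputs is the union of the sketches", {
  pat <- symmetricPattern(5, 2)
  sp <- shuffleSpace(pat, a = 1, seed = 3)
  s1 <- randomSeq(1500, 21)
  s2 <- randomSeq(900, 22)
  both <- sketchSequences(c(s1, s2), pat, sp, format = "seq")
  a <- sketchSequences(s1, pat, sp, format = "seq")
  b <- sketchSequences(s2, pat, sp, format = "seq")
  expect_identical(sketchCodes(both),
                   sort(union(sketchCodes(a), sketchCodes(b))))
})

test_that("expected sketch size is |A|/N on average over shuffle seeds", {
  # scaled-down screen of the unbiased-reduction law (the acceptance suite
  # runs the full 100,000-k-mer, 200-seed version)
  set.seed(99)
  kmers <- vapply(sample.int(4^8, 5000) - 1, int2base4, "", width = 8)
  pat <- selectionPattern("00111100")
  sizes <- vapply(1:60, function(seed) {
    sp <- shuffleSpace(4, a = 2, seed = seed)
    sketchSize(pkgSketchSet(kmers, pat, sp))
  }, 0)
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - 5000 / 16), 3 * se)
})

test_that("FASTA and FASTQ inputs (plain and gzipped) sketch identically", {
  pat <- symmetricPattern(4, 2)
  sp <- shuffleSpace(pat, a = 1, seed = 5)
  seqs <- c(r1 = randomSeq(300, 1), r2 = randomSeq(250, 2))
  fa <- tempfile(fileext = ".fa")
  writeFasta(seqs, fa)
  fq <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@", names(seqs)), seqs, "+",
                             vapply(nchar(seqs), strrep, "", x = "I"))), fq)
  fagz <- tempfile(fileext = ".fa.gz")
  con <- gzfile(fagz, "wb")
  writeLines(readLines(fa), con)
  close(con)
  ref <- sketchSequences(unname(seqs), pat, sp, format = "seq")
  for (f in c(fa, fq, fagz)) {
    expect_identical(sketchCodes(sketchSequences(f, pat, sp)),
                     sketchCodes(ref))
  }
  expect_error(sketchSequences("/nonexistent/file.fa", pat, sp,
                               format = "fasta"), "I/O error")
})

test_that("sketch databases round-trip and enforce their invariants", {
  pat <- symmetricPattern(4, 2)
  sp <- shuffleSpace(pat, a = 1, seed = 5)
  sk <- lapply(1:3, function(i) {
    sketchSequences(randomSeq(400, i), pat, sp, sampleId = paste0("g", i),
                    format = "seq")
  })
  db <- sketchDB(sk)
  expect_identical(length(db), 3L)
  expect_identical(names(db), c("g1", "g2", "g3"))
  path <- tempfile()
  writeSketchDB(db, path)
  back <- readSketchDB(path)
  expect_identical(length(back), 3L)
  for (i in 1:3) {
    expect_identical(sketchCodes(back[[i]]), sketchCodes(db[[i]]))
    expect_identical(sampleId(back[[i]]), sampleId(db[[i]]))
    expect_identical(fingerprint(back[[i]]), fingerprint(db[[i]]))
  }

  # different shuffled spaces cannot be mixed
  spB <- shuffleSpace(pat, a = 1, seed = 6)
  skB <- sketchSequences(randomSeq(400, 9), pat, spB, sampleId = "other",
                         format = "seq")
  expect_error(sketchDB(c(sk, list(skB))), "incompatible-sketch")

  # empty DB round-trips
  e <- sketchDB()
  pe <- tempfile()
  writeSketchDB(e, pe)
  expect_identical(length(readSketchDB(pe)), 0L)

  # truncation is refused
  bytes <- readBin(path, "raw", file.size(path))
  tr <- tempfile()
  writeBin(bytes[1:(length(bytes) - 8L)], tr)
  expect_error(readSketchDB(tr), "corrupt-file")
})
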