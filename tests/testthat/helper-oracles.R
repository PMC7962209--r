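# Independent oracles: everything here works on strings and plain R sets,
# never through the package's packed-integer scanning path.

.BASES <- c("A", "C", "G", "T")

oracleRevcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

oracleCanonical <- function(x) {
  x <- toupper(x)
  rc <- oracleRevcomp(x)
  ifelse(rc < x, rc, x)
}

# all valid length-k windows of a set of sequences, as strings (with
# multiplicity); windows containing non-ACGT characters are dropped
oracleWindows <- function(seqs, k) {
  unlist(lapply(toupper(seqs), function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    win <- substring(s, 1:(n - k + 1), k:n)
    win[!grepl("[^ACGT]", win)]
  }), use.names = FALSE)
}

# the distinct (canonical) k-mer set of a dataset, as strings
oracleKmerSet <- function(seqs, k, canonical = TRUE) {
  win <- oracleWindows(seqs, k)
  if (canonical) win <- oracleCanonical(win)
  sort(unique(win))
}

base4val <- function(s) {
  if (!nchar(s)) return(0)
  d <- match(strsplit(s, "")[[1]], .BASES) - 1
  sum(d * 4^((nchar(s) - 1):0))
}

int2base4 <- function(v, width) {
  if (width == 0) return("")
  d <- integer(width)
  for (i in width:1) {
    d[i] <- v %% 4
    v <- v %/% 4
  }
  paste(.BASES[d + 1], collapse = "")
}

# string-level recoding of one k-mer: select/unselect by pattern characters,
# look up the shuffled rank, build the recoded string, read it in base 4
oracleRecode <- function(kmer, patternStr, space, canonical = FALSE) {
  if (canonical) kmer <- oracleCanonical(kmer)
  chars <- strsplit(toupper(kmer), "")[[1]]
  bits <- strsplit(patternStr, "")[[1]] == "1"
  p1 <- paste(chars[bits], collapse = "")
  p0 <- paste(chars[!bits], collapse = "")
  pos <- space@perm[base4val(p1) + 1]
  nsub <- 4^(space@w - space@a)
  if (pos %/% nsub != space@chosen) return(NA_real_)
  base4val(paste0(p0, int2base4(pos %% nsub, space@w - space@a)))
}

# sketch a k-mer set (strings) through the string-level recoder
oracleSketchSet <- function(kmers, patternStr, space) {
  codes <- vapply(kmers, oracleRecode, 0, patternStr = patternStr,
                  space = space, USE.NAMES = FALSE)
  sort(unique(codes[!is.na(codes)]))
}

# sketch a k-mer set through the package path by feeding each k-mer as its
# own record (canonicalization is idempotent on canonical sets)
pkgSketchSet <- function(kmers, pattern, space, canonical = FALSE) {
  suppressWarnings(
    sketchSequences(kmers, pattern, space, canonical = canonical,
                    format = "seq"))
}

# a Sketch object with arbitrary codes, for estimator unit tests
makeSketch <- function(codes, id = "s", fp = testFingerprint()) {
  new("Sketch", sampleId = id, codes = as.numeric(codes), kmerTotal = NA_real_,
      fingerprint = fp)
}

testFingerprint <- function(k = 12L, a = 1L) {
  list(pattern = strrep("1", k), k = k, w = k, a = a, seed = 1L, chosen = 0L,
       minOcc = 1L, canonical = TRUE, checksum = "deadbeefdeadbeef")
}

randomSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

manualPearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
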