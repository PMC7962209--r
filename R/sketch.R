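.revcompChr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Canonical form of a k-mer
#'
#' The canonical k-mer is the lexicographically smaller of a k-mer and its
#' reverse complement; sketching canonical k-mers makes sketches independent
#' of which strand a sequence happens to be reported on.
#'
#' @param kmer character vector of DNA strings (ACGT, case-insensitive).
#' @return character vector of canonical k-mers (uppercased).
#' @examples
#' canonicalKmer(c("ACGT", "TT", "GAT"))  # "ACGT" "AA" "ATC"
#' @export
canonicalKmer <- function(kmer) {
  up <- toupper(kmer)
  rc <- .revcompChr(up)
  ifelse(rc < up, rc, up)
}

.fingerprint <- function(pattern, space, minOcc, canonical) {
  list(pattern = pattern@pattern, k = pattern@k, w = pattern@w, a = space@a,
       seed = space@seed, chosen = space@chosen,
       minOcc = as.integer(minOcc), canonical = isTRUE(canonical),
       checksum = space@checksum)
}

.checkPatternSpace <- function(pattern, space) {
  if (pattern@w != space@w)
    stop("parameter error: pattern weight (", pattern@w,
         ") does not match the shuffled-space substring length (", space@w, ")")
}

.asPattern <- function(pattern) {
  if (is(pattern, "SelectionPattern")) pattern else selectionPattern(pattern)
}

#' Recode one k-mer against a shuffled space
#'
#' Applies the injective recoding \code{r(K)}: if the selected substring of
#' \code{K} is a member of the chosen subspace, the unselected substring is
#' concatenated (in the high-order position) with the in-subspace rank string
#' of the selected substring, and the resulting \code{(k-a)}-letter string is
#' returned as its base-4 integer.  K-mers whose selected substring falls
#' outside the chosen subspace return \code{NA}.
#'
#' @param kmer a single DNA k-mer of the pattern's length.
#' @param pattern a [SelectionPattern-class] or pattern string.
#' @param space a [ShuffledSpace-class] with matching substring length.
#' @param canonical replace the k-mer by its canonical form first.
#' @return numeric code in \code{[0, 4^(k-a))}, or \code{NA} if not selected.
#' @export
recodeKmer <- function(kmer, pattern, space, canonical = FALSE) {
  pattern <- .asPattern(pattern)
  .checkPatternSpace(pattern, space)
  if (length(kmer) != 1L || nchar(kmer) != pattern@k)
    stop("parameter error: k-mer length must equal the pattern length ",
         pattern@k)
  if (grepl("[^ACGTacgt]", kmer))
    stop("parameter error: k-mer must be over {A,C,G,T}")
  res <- sketch_codes(kmer, pattern@pattern, space@perm, space@a,
                      space@chosen, 1L, canonical)
  if (length(res$codes)) res$codes else NA_real_
}

.isFastqFile <- function(path) {
  grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)
}

.readSequenceFile <- function(path, format = "auto") {
  if (format == "auto") format <- if (.isFastqFile(path)) "fastq" else "fasta"
  as.character(Biostrings::readDNAStringSet(path, format = format))
}

# Accepts a DNAStringSet, raw sequence strings, or file paths (FASTA/FASTQ,
# optionally gzipped; "-" reads standard input).  With format = "auto",
# character input is treated as file paths when every entry exists on disk.
.readSequences <- function(input, format = "auto") {
  if (is(input, "XStringSet")) return(as.character(input))
  if (!is.character(input)) stop("I/O error: unsupported input type")
  if (format == "seq") return(input)
  isStdin <- input == "-"
  if (all(file.exists(input) | isStdin)) {
    unlist(lapply(seq_along(input), function(i) {
      if (isStdin[i]) {
        lines <- readLines(file("stdin"))
        tmp <- tempfile()
        on.exit(unlink(tmp), add = TRUE)
        writeLines(lines, tmp)
        fmt <- if (format == "auto") {
          if (startsWith(trimws(lines[1]), "@")) "fastq" else "fasta"
        } else format
        .readSequenceFile(tmp, fmt)
      } else {
        tryCatch(.readSequenceFile(input[i], format),
                 error = function(e) stop("I/O error reading '", input[i],
                                          "': ", conditionMessage(e)))
      }
    }), use.names = FALSE)
  } else if (format %in% c("fasta", "fastq")) {
    missing <- input[!file.exists(input)]
    stop("I/O error: input file not found: ", paste(missing, collapse = ", "))
  } else {
    if (any(file.exists(input)))
      stop("I/O error: inputs mix existing file paths and raw sequences; ",
           "pass format = 'seq' or format = 'fasta'/'fastq'")
    input
  }
}

#' Sketch a sequence dataset
#'
#' Streams every record, scans all length-k windows (0-based, half-open;
#' windows containing a non-ACGT character are skipped), canonicalizes
#' k-mers when \code{canonical = TRUE}, keeps those whose selected substring
#' lies in the chosen subspace, applies the injective recoding, filters by
#' occurrence and returns the sorted deduplicated code set.
#'
#' Occurrence counts are tallied only for k-mers already selected into the
#' subspace, so the memory footprint scales with the sketch, not the k-mer
#' set.  Counts are per call — a sample spanning several files should be
#' sketched in one call.
#'
#' @param input sequences: a \code{DNAStringSet}, a character vector of raw
#'   sequences, or FASTA/FASTQ file paths (plain or gzipped; \code{"-"} for
#'   standard input).
#' @param pattern a [SelectionPattern-class] or pattern string.
#' @param space a [ShuffledSpace-class] whose substring length matches the
#'   pattern weight.
#' @param minOcc keep a k-mer only if it occurred at least this many times
#'   (read sets are typically sketched with \code{minOcc = 2} to drop
#'   sequencing-error k-mers).
#' @param canonical sketch canonical k-mers (default).  With an asymmetric
#'   pattern canonical sketches are not strand-invariant and a warning is
#'   emitted.
#' @param sampleId sample label stored in the sketch.
#' @param format \code{"auto"}, \code{"fasta"}, \code{"fastq"}, or
#'   \code{"seq"} (treat character input as raw sequences).
#' @return A [Sketch-class].
#' @examples
#' sp <- shuffleSpace(2, a = 1, seed = 1)
#' sketchSequences("ACGTACGGT", symmetricPattern(6, 1), sp, format = "seq")
#' @export
sketchSequences <- function(input, pattern, space, minOcc = 1L,
                            canonical = TRUE, sampleId = "sample",
                            format = "auto") {
  pattern <- .asPattern(pattern)
  .checkPatternSpace(pattern, space)
  if (minOcc < 1L) stop("parameter error: minOcc must be >= 1")
  if (canonical && !pattern@symmetric)
    warning("canonical sketching with an asymmetric pattern is not ",
            "strand-invariant")
  seqs <- .readSequences(input, format)
  res <- sketch_codes(seqs, pattern@pattern, space@perm, space@a,
                      space@chosen, as.integer(minOcc), canonical)
  if (!length(res$codes))
    warning("empty sketch for sample '", sampleId, "'")
  new("Sketch", sampleId = as.character(sampleId), codes = res$codes,
      kmerTotal = res$kmer_total,
      fingerprint = .fingerprint(pattern, space, minOcc, canonical))
}

#' @rdname accessors
#' @export
setMethod("sampleId", "Sketch", function(x) x@sampleId)

#' Accessors for sketches and sketch databases
#'
#' \code{sampleId()}, \code{sketchCodes()}, \code{sketchSize()} (the number
#' of codes, \code{|S(A)|}), \code{kmerTotal()} (valid windows scanned) and
#' \code{fingerprint()} (the comparability parameters).
#' \code{subspaceCount()} and \code{spaceChecksum()} read a
#' [ShuffledSpace-class].
#'
#' @param x a [Sketch-class], [SketchDB-class], [Decomposition-class] or
#'   [ShuffledSpace-class] as appropriate.
#' @param space a [ShuffledSpace-class].
#' @name accessors
#' @export
setMethod("sketchCodes", "Sketch", function(x) x@codes)

#' @rdname accessors
#' @export
setMethod("sketchSize", "Sketch", function(x) length(x@codes))

#' @rdname accessors
#' @export
setMethod("kmerTotal", "Sketch", function(x) x@kmerTotal)

#' @rdname accessors
#' @export
setMethod("fingerprint", "Sketch", function(x) x@fingerprint)

#' @rdname accessors
#' @export
setMethod("fingerprint", "SketchDB", function(x) x@fingerprint)

setMethod("show", "Sketch", function(object) {
  fp <- object@fingerprint
  cat("Sketch '", object@sampleId, "': ",
      format(length(object@codes), big.mark = ","), " codes from ",
      format(object@kmerTotal, big.mark = ","), " k-mer windows\n", sep = "")
  cat("  k = ", fp$k, ", w = ", fp$w, ", N = 4^", fp$a,
      ", subspace ", fp$chosen, ", minOcc = ", fp$minOcc,
      ", canonical = ", fp$canonical, "\n", sep = "")
  cat("  space seed = ", fp$seed, ", checksum = ", fp$checksum, "\n", sep = "")
})

#' Build a sketch database
#'
#' A SketchDB is an ordered collection of sketches sharing one parameter
#' fingerprint — the in-memory form of the combined sketch used for
#' all-vs-all comparison.
#'
#' @param ... [Sketch-class] objects, or a single list of them.
#' @return A [SketchDB-class].
#' @export
sketchDB <- function(...) {
  sk <- list(...)
  if (length(sk) == 1L && is.list(sk[[1]]) && !is(sk[[1]], "Sketch"))
    sk <- sk[[1]]
  fp <- if (length(sk)) sk[[1]]@fingerprint else list()
  for (s in sk) {
    if (!is(s, "Sketch")) stop("all arguments must be Sketch objects")
    if (!identical(s@fingerprint, fp))
      stop("incompatible-sketch error: fingerprints differ within the database")
  }
  new("SketchDB", sketches = sk, fingerprint = fp)
}

#' @export
setMethod("length", "SketchDB", function(x) length(x@sketches))

#' @export
setMethod("names", "SketchDB",
          function(x) vapply(x@sketches, function(s) s@sampleId, ""))

#' @export
setMethod("[[", "SketchDB", function(x, i, j, ...) {
  if (is.character(i)) i <- match(i, names(x))
  x@sketches[[i]]
})

setMethod("show", "SketchDB", function(object) {
  cat("SketchDB with ", length(object@sketches), " sketch(es)\n", sep = "")
  if (length(object@sketches)) {
    fp <- object@fingerprint
    cat("  k = ", fp$k, ", w = ", fp$w, ", N = 4^", fp$a,
        ", checksum = ", fp$checksum, "\n", sep = "")
    sizes <- vapply(object@sketches, function(s) length(s@codes), 0)
    cat("  samples: ", paste(utils::head(names(object), 5), collapse = ", "),
        if (length(object@sketches) > 5) ", ..." else "",
        " (sizes ", paste(utils::head(sizes, 5), collapse = ", "), ")\n",
        sep = "")
  }
})

.DB_MAGIC <- "KSDB"
.DB_VERSION <- 1L

.writeStr <- function(con, s) {
  r <- charToRaw(s)
  writeBin(length(r), con, size = 4L)
  writeBin(r, con)
}

.readStr <- function(con) {
  n <- readBin(con, "integer", 1L, size = 4L)
  if (!length(n)) stop("corrupt-file error: truncated sketch database")
  r <- readBin(con, "raw", n)
  if (length(r) != n) stop("corrupt-file error: truncated sketch database")
  rawToChar(r)
}

.writeFingerprint <- function(con, fp) {
  .writeStr(con, fp$pattern)
  writeBin(as.integer(c(fp$k, fp$w, fp$a, fp$seed, fp$chosen, fp$minOcc,
                        fp$canonical)), con, size = 4L)
  .writeStr(con, fp$checksum)
}

.readFingerprint <- function(con) {
  pattern <- .readStr(con)
  v <- readBin(con, "integer", 7L, size = 4L)
  if (length(v) != 7L) stop("corrupt-file error: truncated fingerprint")
  list(pattern = pattern, k = v[1], w = v[2], a = v[3], seed = v[4],
       chosen = v[5], minOcc = v[6], canonical = as.logical(v[7]),
       checksum = .readStr(con))
}

#' Persist and reload a sketch database
#'
#' Versioned binary format: magic, version, shared fingerprint, then one
#' block per sample (id, window total, code count, raw 64-bit code array),
#' closed by an end marker so truncation is detected.
#'
#' @param db a [SketchDB-class].
#' @param path file path.
#' @return \code{readSketchDB()} returns the [SketchDB-class];
#'   \code{writeSketchDB()} returns \code{path} invisibly.
#' @export
writeSketchDB <- function(db, path) {
  stopifnot(is(db, "SketchDB"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.DB_MAGIC), con)
  writeBin(.DB_VERSION, con, size = 4L)
  writeBin(length(db@sketches), con, size = 4L)
  if (length(db@sketches)) .writeFingerprint(con, db@fingerprint)
  for (s in db@sketches) {
    .writeStr(con, s@sampleId)
    writeBin(s@kmerTotal, con, size = 8L)
    writeBin(length(s@codes), con, size = 4L)
    writeBin(s@codes, con, size = 8L)
  }
  writeBin(charToRaw("KEND"), con)
  invisible(path)
}

#' @rdname writeSketchDB
#' @export
readSketchDB <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, .DB_MAGIC))
    stop("corrupt-file error: not a sketch database (bad magic)")
  ver <- readBin(con, "integer", 1L, size = 4L)
  if (!identical(ver, .DB_VERSION))
    stop("corrupt-file error: unknown sketch database version ", ver)
  nsk <- readBin(con, "integer", 1L, size = 4L)
  fp <- if (nsk > 0L) .readFingerprint(con) else list()
  sketches <- vector("list", nsk)
  for (i in seq_len(nsk)) {
    id <- .readStr(con)
    kt <- readBin(con, "double", 1L, size = 8L)
    nc <- readBin(con, "integer", 1L, size = 4L)
    if (!length(kt) || !length(nc))
      stop("corrupt-file error: truncated sketch database")
    codes <- readBin(con, "double", nc, size = 8L)
    if (length(codes) != nc)
      stop("corrupt-file error: truncated code array for sample '", id, "'")
    sketches[[i]] <- new("Sketch", sampleId = id, codes = codes,
                         kmerTotal = kt, fingerprint = fp)
  }
  end <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(end, "KEND"))
    stop("corrupt-file error: sketch database end marker missing")
  new("SketchDB", sketches = sketches, fingerprint = fp)
}
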