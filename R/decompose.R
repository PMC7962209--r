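#' Decompose a sequence dataset across all subspaces
#'
#' Applies the sketching map with every one of the \code{N = 4^a} subspaces
#' of a shuffled space, so each distinct (canonical) k-mer lands in exactly
#' one component sketch.  The components are pairwise disjoint, their sizes
#' sum to the number of distinct k-mers, and concatenating them reproduces
#' the full injectively recoded k-mer set — decomposition loses nothing, it
#' only shards the set so each piece takes about \code{1/N} of the memory.
#'
#' @inheritParams sketchSequences
#' @return A [Decomposition-class] with \code{4^a} components in subspace
#'   order.
#' @seealso [exactJaccard()], [exactContainment()]
#' @export
decomposeSequences <- function(input, pattern, space, minOcc = 1L,
                               canonical = TRUE, sampleId = "sample",
                               format = "auto") {
  pattern <- .asPattern(pattern)
  .checkPatternSpace(pattern, space)
  if (minOcc < 1L) stop("parameter error: minOcc must be >= 1")
  if (canonical && !pattern@symmetric)
    warning("canonical decomposition with an asymmetric pattern is not ",
            "strand-invariant")
  seqs <- .readSequences(input, format)
  res <- decompose_codes(seqs, pattern@pattern, space@perm, space@a,
                         as.integer(minOcc), canonical)
  fp <- .fingerprint(pattern, space, minOcc, canonical)
  fp$chosen <- NA_integer_
  new("Decomposition", sampleId = as.character(sampleId),
      components = res$components, kmerTotal = res$kmer_total,
      fingerprint = fp)
}

#' @rdname accessors
#' @export
setMethod("sampleId", "Decomposition", function(x) x@sampleId)

#' @rdname accessors
#' @export
components <- function(x) {
  stopifnot(is(x, "Decomposition"))
  x@components
}

#' @rdname accessors
#' @export
setMethod("sketchSize", "Decomposition",
          function(x) sum(lengths(x@components)))

#' @rdname accessors
#' @export
setMethod("kmerTotal", "Decomposition", function(x) x@kmerTotal)

#' @rdname accessors
#' @export
setMethod("fingerprint", "Decomposition", function(x) x@fingerprint)

setMethod("show", "Decomposition", function(object) {
  fp <- object@fingerprint
  cat("Decomposition '", object@sampleId, "': ",
      length(object@components), " components, ",
      format(sum(lengths(object@components)), big.mark = ","),
      " distinct k-mers\n", sep = "")
  cat("  k = ", fp$k, ", w = ", fp$w, ", N = 4^", fp$a,
      ", checksum = ", fp$checksum, "\n", sep = "")
})

.checkDecompComparable <- function(x, y) {
  if (!identical(x@fingerprint, y@fingerprint))
    stop("incompatible-sketch error: decompositions were built with ",
         "different parameters or shuffled spaces")
}

#' Exact Jaccard and containment via decomposition
#'
#' Streams the two decompositions one subspace at a time, accumulating
#' per-component intersection and union (or total) sizes; the ratios of the
#' sums are the exact Jaccard and containment coefficients of the full
#' k-mer sets, recovered without ever holding either set whole in memory.
#'
#' @param x,y [Decomposition-class] objects over the same shuffled space.
#' @return numeric in \code{[0, 1]}.
#' @rdname exactJaccard
#' @export
setMethod("exactJaccard", signature("Decomposition", "Decomposition"),
  function(x, y) {
    .checkDecompComparable(x, y)
    sh <- un <- 0
    for (i in seq_along(x@components)) {
      s <- .sharedCount(x@components[[i]], y@components[[i]])
      sh <- sh + s
      un <- un + length(x@components[[i]]) + length(y@components[[i]]) - s
    }
    if (un == 0) stop("parameter error: Jaccard undefined for two empty sets")
    sh / un
  })

#' @rdname exactJaccard
#' @export
setMethod("exactContainment", signature("Decomposition", "Decomposition"),
  function(x, y) {
    .checkDecompComparable(x, y)
    sh <- 0
    for (i in seq_along(x@components))
      sh <- sh + .sharedCount(x@components[[i]], y@components[[i]])
    mn <- min(sum(lengths(x@components)), sum(lengths(y@components)))
    if (mn == 0) stop("parameter error: containment undefined for an empty set")
    sh / mn
  })

#' Persist and reload a decomposition
#'
#' Stored as a sharded sketch database: one shard per subspace, in subspace
#' order, in the same versioned binary container as [writeSketchDB()].
#'
#' @param d a [Decomposition-class].
#' @param path file path.
#' @return \code{readDecomposition()} returns the [Decomposition-class];
#'   \code{writeDecomposition()} returns \code{path} invisibly.
#' @export
writeDecomposition <- function(d, path) {
  stopifnot(is(d, "Decomposition"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("KSDC"), con)
  writeBin(.DB_VERSION, con, size = 4L)
  .writeStr(con, d@sampleId)
  fp <- d@fingerprint
  fp$chosen <- -1L  # NA marker in the fixed-width header
  .writeFingerprint(con, fp)
  writeBin(d@kmerTotal, con, size = 8L)
  writeBin(length(d@components), con, size = 4L)
  for (comp in d@components) {
    writeBin(length(comp), con, size = 4L)
    writeBin(comp, con, size = 8L)
  }
  writeBin(charToRaw("KEND"), con)
  invisible(path)
}

#' @rdname writeDecomposition
#' @export
readDecomposition <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, "KSDC"))
    stop("corrupt-file error: not a decomposition file (bad magic)")
  ver <- readBin(con, "integer", 1L, size = 4L)
  if (!identical(ver, .DB_VERSION))
    stop("corrupt-file error: unknown decomposition version ", ver)
  id <- .readStr(con)
  fp <- .readFingerprint(con)
  fp$chosen <- NA_integer_
  kt <- readBin(con, "double", 1L, size = 8L)
  nc <- readBin(con, "integer", 1L, size = 4L)
  if (!length(kt) || !length(nc))
    stop("corrupt-file error: truncated decomposition file")
  comps <- vector("list", nc)
  for (i in seq_len(nc)) {
    m <- readBin(con, "integer", 1L, size = 4L)
    if (!length(m)) stop("corrupt-file error: truncated decomposition file")
    v <- readBin(con, "double", m, size = 8L)
    if (length(v) != m) stop("corrupt-file error: truncated component ", i)
    comps[[i]] <- v
  }
  end <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(end, "KEND"))
    stop("corrupt-file error: decomposition end marker missing")
  new("Decomposition", sampleId = id, components = comps, kmerTotal = kt,
      fingerprint = fp)
}
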