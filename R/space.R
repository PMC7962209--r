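#' Shuffle and partition the k-mer substring space
#'
#' Materializes the permutation of all \code{4^w} substring-space dimensions
#' produced by a seeded Fisher-Yates shuffle (descending index, unbiased
#' bounded draws from a splitmix64-seeded xoshiro256++ generator — portable,
#' so identical inputs give byte-identical spaces on any platform).  The
#' shuffled space is partitioned into \code{N = 4^a} equal subspaces of
#' \code{4^(w-a)} dimensions; the \code{chosen} subspace is the one used for
#' sketching.  Because the shuffle is unbiased, the chosen subspace is a
#' uniform sample without replacement of the dimensions, which is what makes
#' downstream Jaccard/containment estimators unbiased.
#'
#' @param x a [SelectionPattern-class] (its weight is used) or the numeric
#'   substring length \code{w}.
#' @param a integer partition exponent, \code{0 <= a <= w}; \code{N = 4^a}.
#'   The command-line convention \code{a = 2z} writes the reduction level
#'   \code{z} in units of 16-fold shrinkage.
#' @param seed integer RNG seed.
#' @param chosen index of the retained subspace in \code{[0, 4^a)};
#'   defaults to the first shuffled block.
#' @param permute if \code{FALSE}, keep the identity permutation (dimensions
#'   in lexical order) — for hand-checkable worked examples only.
#' @param maxW memory cap: the permutation has \code{4^w} entries and is
#'   refused above this weight rather than silently subsampled.
#' @return A [ShuffledSpace-class].
#' @examples
#' sp <- shuffleSpace(2, a = 1, seed = 7)  # 16 dims, 4 subspaces of 4
#' reductionFold(sp)                       # 4
#' @export
shuffleSpace <- function(x, a, seed = 1L, chosen = 0L, permute = TRUE,
                         maxW = getOption("KmerSketch.maxW", 14L)) {
  w <- if (is(x, "SelectionPattern")) x@w else as.integer(x)
  a <- as.integer(a); seed <- as.integer(seed); chosen <- as.integer(chosen)
  if (a < 0L) stop("parameter error: a must be non-negative")
  if (a > w) stop("parameter error: a = ", a, " exceeds w = ", w)
  if (w > maxW)
    stop("resource error: 4^", w, " dimensions exceed the memory cap ",
         "(maxW = ", maxW, "); use a smaller substring weight w")
  if (chosen < 0L || chosen >= 4^a)
    stop("parameter error: chosen subspace must lie in [0, 4^", a, ")")
  n <- 4^w
  perm <- if (permute) fisher_yates_ranks(n, seed) else seq_len(n) - 1L
  new("ShuffledSpace", w = w, a = a, seed = seed, chosen = chosen,
      perm = perm, checksum = space_checksum(perm, w, a))
}

#' @rdname reductionFold
#' @export
reductionLevel <- function(space) {
  stopifnot(is(space, "ShuffledSpace"))
  if (space@a %% 2L == 0L) space@a %/% 2L else NA_integer_
}

#' Dimensionality-reduction fold
#'
#' The expected shrinkage of a k-mer set into its sketch is \code{N = 4^a};
#' in the command-line convention \code{a = 2z} this is \code{16^z}.
#' For a numeric argument \code{z}, returns \code{16^z}.
#'
#' @param x a [ShuffledSpace-class] or a numeric reduction level \code{z}.
#' @return numeric fold.
#' @examples
#' reductionFold(3)  # 4096
#' @rdname reductionFold
#' @export
setMethod("reductionFold", "ShuffledSpace", function(x) 4^x@a)

#' @rdname reductionFold
#' @export
setMethod("reductionFold", "numeric", function(x) {
  stopifnot(x >= 0, x == round(x))
  16^x
})

#' @rdname accessors
#' @export
subspaceCount <- function(space) {
  stopifnot(is(space, "ShuffledSpace"))
  4^space@a
}

#' @rdname accessors
#' @export
spaceChecksum <- function(space) {
  stopifnot(is(space, "ShuffledSpace"))
  space@checksum
}

#' @rdname recodeLength
#' @export
setMethod("recodeLength", "ShuffledSpace",
          function(x, a) as.integer(x@w - x@a))

setMethod("show", "ShuffledSpace", function(object) {
  cat("ShuffledSpace: w = ", object@w, ", |S| = ",
      format(4^object@w, big.mark = ","), " dimensions\n", sep = "")
  z <- reductionLevel(object)
  cat("  N = 4^", object@a, " = ", format(4^object@a, big.mark = ","),
      " subspaces of ", format(4^(object@w - object@a), big.mark = ","),
      " dims (", if (is.na(z)) "no 16-fold level" else
        paste0("level z = ", z, ", ", format(16^z, big.mark = ","), "-fold"),
      ")\n", sep = "")
  cat("  seed = ", object@seed, ", chosen subspace = ", object@chosen,
      ", checksum = ", object@checksum, "\n", sep = "")
})

.SHUF_MAGIC <- "KSHF"
.SHUF_VERSION <- 1L

#' Persist and reload a shuffled space
#'
#' The on-disk ".shuf" file is a small versioned binary: magic, version,
#' header (w, a, seed, chosen), the 32-bit rank table and an FNV-1a content
#' checksum.  \code{readShuf()} verifies magic, version and checksum and
#' refuses truncated or edited files.
#'
#' @param space a [ShuffledSpace-class].
#' @param path file path (conventionally ending in ".shuf").
#' @return \code{readShuf()} returns the [ShuffledSpace-class];
#'   \code{writeShuf()} returns \code{path} invisibly.
#' @export
writeShuf <- function(space, path) {
  stopifnot(is(space, "ShuffledSpace"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.SHUF_MAGIC), con)
  writeBin(c(.SHUF_VERSION, space@w, space@a, space@seed, space@chosen), con,
           size = 4L)
  writeBin(as.numeric(length(space@perm)), con, size = 8L)
  writeBin(space@perm, con, size = 4L)
  writeBin(charToRaw(space@checksum), con)
  invisible(path)
}

#' @rdname writeShuf
#' @export
readShuf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, .SHUF_MAGIC))
    stop("corrupt-file error: not a .shuf file (bad magic)")
  hdr <- readBin(con, "integer", 5L, size = 4L)
  if (length(hdr) < 5L) stop("corrupt-file error: truncated .shuf header")
  if (hdr[1] != .SHUF_VERSION)
    stop("corrupt-file error: unknown .shuf version ", hdr[1])
  n <- readBin(con, "double", 1L, size = 8L)
  if (!length(n)) stop("corrupt-file error: truncated .shuf file")
  perm <- readBin(con, "integer", n, size = 4L)
  if (length(perm) != n) stop("corrupt-file error: truncated .shuf rank table")
  stored <- rawToChar(readBin(con, "raw", 16L))
  cks <- space_checksum(perm, hdr[2], hdr[3])
  if (!identical(stored, cks))
    stop("corrupt-file error: .shuf checksum mismatch")
  new("ShuffledSpace", w = hdr[2], a = hdr[3], seed = hdr[4],
      chosen = hdr[5], perm = perm, checksum = cks)
}
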