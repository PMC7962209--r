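#' Construct a selection pattern
#'
#' \code{selectionPattern()} accepts any "01" string; \code{symmetricPattern()}
#' expands the symmetric template \code{"0"^(x-y) "1"^(2y) "0"^(x-y)} from the
#' half k-mer length \code{x} and half weight \code{y}, giving \code{k = 2x}
#' and \code{w = 2y}.  Only symmetric patterns guarantee strand-independent
#' canonical sketches; general patterns are accepted for didactic worked
#' examples and experimentation.
#'
#' The symmetric constructor enforces \code{12 > x > y >= 1}: \code{x < 12}
#' bounds the code width, \code{x > y} leaves at least one unselected
#' position on each flank.
#'
#' @param pattern character; a string over \{0, 1\}.
#' @param x integer; half k-mer length (k = 2x).
#' @param y integer; half substring weight (w = 2y).
#' @return A [SelectionPattern-class] object.
#' @examples
#' symmetricPattern(6, 1)          # "000001100000", k = 12, w = 2
#' selectionPattern("000010010000") # an asymmetric 12-mer pattern, w = 2
#' @export
selectionPattern <- function(pattern) {
  pattern <- as.character(pattern)
  stopifnot(length(pattern) == 1L, !is.na(pattern))
  if (grepl("[^01]", pattern))
    stop("pattern must contain only '0' and '1'")
  k <- nchar(pattern)
  if (k > 26L)
    stop("parameter error: k = ", k, " exceeds the supported maximum of 26")
  w <- sum(strsplit(pattern, "")[[1]] == "1")
  ones <- gregexpr("1", pattern)[[1]]
  sym <- w > 0L && k %% 2L == 0L && w %% 2L == 0L &&
    ones[1] > 0L && (ones[length(ones)] - ones[1] + 1L) == w &&
    (ones[1] - 1L) == (k - ones[length(ones)])
  new("SelectionPattern", pattern = pattern, k = as.integer(k),
      w = as.integer(w), symmetric = sym)
}

#' @rdname selectionPattern
#' @export
symmetricPattern <- function(x, y) {
  x <- as.integer(x); y <- as.integer(y)
  if (!(x < 12L)) stop("parameter error: constraint 12 > x violated (x = ", x, ")")
  if (!(x > y)) stop("parameter error: constraint x > y violated (x = ", x,
                     ", y = ", y, ")")
  if (!(y >= 1L)) stop("parameter error: constraint y >= 1 violated (y = ", y, ")")
  pat <- paste0(strrep("0", x - y), strrep("1", 2L * y), strrep("0", x - y))
  selectionPattern(pat)
}

#' Pattern weight
#'
#' The weight \code{w} of a selection pattern is its number of 1s — the
#' length of the selected substring cut from each k-mer.
#'
#' @param x a [SelectionPattern-class] or a "01" string.
#' @return integer weight.
#' @examples
#' patternWeight("000010010000") # 2
#' @rdname patternWeight
#' @export
setMethod("patternWeight", "SelectionPattern", function(x) x@w)

#' @rdname patternWeight
#' @export
setMethod("patternWeight", "character",
          function(x) patternWeight(selectionPattern(x)))

#' Dimensionality of the substring space
#'
#' The substring space holds all DNA strings of length \code{w}, one
#' dimension per string, so its dimensionality is \code{4^w}.
#'
#' @param x a [SelectionPattern-class], a pattern string, or a numeric
#'   weight \code{w}.
#' @return numeric; \code{4^w}.
#' @examples
#' spaceDim("000010010000") # 16
#' spaceDim(6)              # 4096
#' @rdname spaceDim
#' @export
setMethod("spaceDim", "SelectionPattern", function(x) 4^x@w)

#' @rdname spaceDim
#' @export
setMethod("spaceDim", "character", function(x) spaceDim(selectionPattern(x)))

#' @rdname spaceDim
#' @export
setMethod("spaceDim", "numeric", function(x) {
  stopifnot(x >= 0, x == round(x))
  4^x
})

#' Length of the recoding string
#'
#' After partitioning the \code{4^w}-dimensional space into \code{N = 4^a}
#' subspaces, each in-subspace dimension is recoded by a lexically ordered
#' string of length \code{log4(4^w / 4^a) = w - a}.
#'
#' @param x a [SelectionPattern-class], [ShuffledSpace-class], pattern string,
#'   or numeric weight \code{w}.
#' @param a integer partition exponent (ignored for \code{ShuffledSpace},
#'   which carries its own).
#' @return integer; \code{w - a}.
#' @examples
#' recodeLength(2, 1)  # 1: D = 16, N = 4
#' @rdname recodeLength
#' @export
setMethod("recodeLength", "numeric", function(x, a) {
  a <- as.integer(a)
  if (a > x) stop("parameter error: a must not exceed w")
  as.integer(x - a)
})

#' @rdname recodeLength
#' @export
setMethod("recodeLength", "SelectionPattern", function(x, a) recodeLength(x@w, a))

#' @rdname recodeLength
#' @export
setMethod("recodeLength", "character",
          function(x, a) recodeLength(patternWeight(x), a))

setMethod("show", "SelectionPattern", function(object) {
  cat("SelectionPattern \"", object@pattern, "\"\n", sep = "")
  cat("  k = ", object@k, ", weight w = ", object@w,
      if (object@symmetric) " (symmetric)" else " (asymmetric)",
      ", |S| = 4^w = ", format(4^object@w, big.mark = ","), "\n", sep = "")
})
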