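#' @useDynLib KmerSketch, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats cor pnorm runif rbinom
#' @importFrom utils write.table
NULL

#' SelectionPattern: which k-mer positions form the selected substring
#'
#' A selection pattern is a "01" string of length \code{k}.  The letters of a
#' k-mer at the pattern's 1-positions are concatenated into the
#' \emph{selected} substring (length \code{w}, the pattern weight); the
#' letters at the 0-positions form the \emph{unselected} substring.  The
#' selected substring decides whether a k-mer enters the sketch; the
#' unselected substring is carried through the recoding unchanged, which is
#' what makes the k-mer-to-integer map injective.
#'
#' Symmetric patterns (a centred run of 1s, \code{"0"^(x-y) "1"^(2y)
#' "0"^(x-y)} with \code{k = 2x}, \code{w = 2y}) commute with reverse
#' complementation, so canonical-k-mer sketches built from them are
#' strand-independent.
#'
#' @slot pattern character; the "01" string.
#' @slot k integer; k-mer length, \code{nchar(pattern)}.
#' @slot w integer; weight, the number of 1s.
#' @slot symmetric logical; TRUE when the pattern is a centred 1-run with
#'   even \code{k} and \code{w}.
#' @seealso [selectionPattern()], [symmetricPattern()]
#' @export
setClass("SelectionPattern",
  representation(pattern = "character", k = "integer", w = "integer",
                 symmetric = "logical"),
  validity = function(object) {
    p <- object@pattern
    if (length(p) != 1L || is.na(p)) return("pattern must be a single string")
    if (grepl("[^01]", p)) return("pattern must contain only '0' and '1'")
    if (nchar(p) != object@k) return("k must equal nchar(pattern)")
    if (lengths(regmatches(p, gregexpr("1", p))) != object@w &&
        !(object@w == 0L && !grepl("1", p)))
      return("w must equal the number of 1s in pattern")
    TRUE
  })

#' ShuffledSpace: the shuffled, partitioned k-mer substring space
#'
#' The substring space is the set of all \code{4^w} DNA strings of length
#' \code{w}; each string is one dimension.  The space is Fisher-Yates
#' shuffled with a seeded, portable RNG and partitioned into \code{N = 4^a}
#' subspaces of equal size \code{4^(w-a)}.  One subspace is chosen for
#' sketching; a k-mer is kept iff its selected substring lies in it, giving
#' an expected dimensionality-reduction rate of \code{1/N}.
#'
#' @slot w integer; substring length (pattern weight).
#' @slot a integer; partition exponent, \code{0 <= a <= w}.
#' @slot seed integer; RNG seed of the shuffle.
#' @slot chosen integer; index of the chosen subspace in \code{[0, 4^a)}.
#' @slot perm integer vector of length \code{4^w}; \code{perm[d + 1]} is the
#'   shuffled rank of dimension \code{d}.  Ranks in block
#'   \code{[chosen*4^(w-a), (chosen+1)*4^(w-a))} are members of the chosen
#'   subspace; the offset within the block is the in-subspace rank.
#' @slot checksum character; 64-bit FNV-1a fingerprint of \code{(w, a, perm)}.
#' @seealso [shuffleSpace()], [writeShuf()], [readShuf()]
#' @export
setClass("ShuffledSpace",
  representation(w = "integer", a = "integer", seed = "integer",
                 chosen = "integer", perm = "integer", checksum = "character"),
  validity = function(object) {
    if (object@a > object@w) return("a must not exceed w")
    if (object@a < 0L) return("a must be non-negative")
    if (length(object@perm) != 4^object@w)
      return("perm must have 4^w entries")
    if (object@chosen < 0L || object@chosen >= 4^object@a)
      return("chosen subspace index out of [0, 4^a)")
    TRUE
  })

#' Sketch: one sample's reduced, recoded k-mer set
#'
#' Codes are the sorted, deduplicated integers \code{r(K)} of the sample's
#' selected k-mers: the unselected substring in the high-order bits, the
#' in-subspace rank of the selected substring as the suffix.  Each code
#' occupies \code{2(k - a)} bits and is stored exactly as a double
#' (\code{k <= 26}).  The fingerprint records every parameter that must match
#' for two sketches to be comparable.
#'
#' @slot sampleId character; sample label.
#' @slot codes numeric; strictly increasing recoded k-mer integers.
#' @slot kmerTotal numeric; number of valid length-k windows scanned.
#' @slot fingerprint list with elements \code{pattern, k, w, a, seed, chosen,
#'   minOcc, canonical, checksum}.
#' @seealso [sketchSequences()], [jaccardEstimate()]
#' @export
setClass("Sketch",
  representation(sampleId = "character", codes = "numeric",
                 kmerTotal = "numeric", fingerprint = "list"),
  validity = function(object) {
    cd <- object@codes
    if (anyNA(cd)) return("codes must not contain NA")
    if (is.unsorted(cd, strictly = TRUE)) return("codes must be strictly increasing")
    fp <- object@fingerprint
    need <- c("pattern", "k", "w", "a", "seed", "chosen", "minOcc",
              "canonical", "checksum")
    if (!all(need %in% names(fp)))
      return(paste("fingerprint must contain:", paste(need, collapse = ", ")))
    if (length(cd) && max(cd) >= 4^(fp$k - fp$a))
      return("codes must be < 4^(k-a)")
    TRUE
  })

#' SketchDB: an ordered collection of fingerprint-compatible sketches
#'
#' The on-disk form is the "combined sketch" used for all-vs-all comparison:
#' every member shares one parameter fingerprint and sample ids are unique.
#'
#' @slot sketches list of [Sketch-class] objects.
#' @slot fingerprint list; the shared fingerprint (empty DB allowed).
#' @seealso [sketchDB()], [writeSketchDB()], [allVsAll()]
#' @export
setClass("SketchDB",
  representation(sketches = "list", fingerprint = "list"),
  validity = function(object) {
    if (!all(vapply(object@sketches, is, TRUE, "Sketch")))
      return("all members must be Sketch objects")
    ids <- vapply(object@sketches, function(s) s@sampleId, "")
    if (anyDuplicated(ids)) return("sample ids must be unique")
    if (length(object@sketches)) {
      for (s in object@sketches)
        if (!identical(s@fingerprint, object@fingerprint))
          return("all sketches must share the DB fingerprint")
    }
    TRUE
  })

#' Decomposition: a k-mer set split into its N per-subspace sketches
#'
#' Applying the sketching map with every one of the \code{N = 4^a} subspaces
#' decomposes a k-mer set into pairwise-disjoint components whose sizes sum
#' to the number of distinct (canonical) k-mers.  Exact Jaccard and
#' containment are recovered component by component, each step touching only
#' about \code{1/N} of the k-mer set.
#'
#' @slot sampleId character.
#' @slot components list of numeric vectors, one sorted code set per
#'   subspace, in subspace order.
#' @slot kmerTotal numeric; valid windows scanned.
#' @slot fingerprint list as for [Sketch-class]; \code{chosen} is \code{NA}.
#' @seealso [decomposeSequences()], [exactJaccard()]
#' @export
setClass("Decomposition",
  representation(sampleId = "character", components = "list",
                 kmerTotal = "numeric", fingerprint = "list"),
  validity = function(object) {
    fp <- object@fingerprint
    if (length(object@components) != 4^fp$a)
      return("must have exactly 4^a components")
    TRUE
  })

#' MutationGrid: design of an in-silico evolution experiment
#'
#' A reference genome length plus an ordered grid of per-base substitution
#' rates; each rate gets a deterministically derived child seed so the whole
#' experiment is reproducible from one master seed.
#'
#' @slot referenceLength numeric; reference genome length in bp.
#' @slot rates numeric; strictly increasing substitution rates in (0, 1).
#' @slot seed integer; master seed.
#' @seealso [mutationGrid()], [accuracyExperiment()]
#' @export
setClass("MutationGrid",
  representation(referenceLength = "numeric", rates = "numeric",
                 seed = "integer"),
  validity = function(object) {
    r <- object@rates
    if (!length(r)) return("rates must be non-empty")
    if (any(r <= 0 | r >= 1)) return("rates must lie in (0, 1)")
    if (is.unsorted(r, strictly = TRUE)) return("rates must be strictly increasing")
    TRUE
  })
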