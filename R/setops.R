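.opFingerprint <- function(fps) {
  # set-operation results may mix minOcc provenance; everything else must match
  strip <- function(fp) fp[setdiff(names(fp), "minOcc")]
  base <- fps[[1]]
  for (fp in fps[-1]) {
    if (!identical(strip(fp), strip(base)))
      stop("incompatible-sketch error: sketches were built with different ",
           "parameters or shuffled spaces")
  }
  occs <- unique(vapply(fps, function(fp) fp$minOcc, 0L))
  if (length(occs) > 1L) base$minOcc <- NA_integer_  # "mixed" provenance
  base
}

.newOpSketch <- function(id, codes, fps) {
  new("Sketch", sampleId = id, codes = as.numeric(codes),
      kmerTotal = NA_real_, fingerprint = .opFingerprint(fps))
}

#' Exact set algebra on sketches
#'
#' Because the k-mer recoding is injective, set operations commute with
#' sketching: the union/intersection/difference of two sketches equals the
#' sketch of the union/intersection/difference of the underlying k-mer sets.
#' \code{sketchUnion()} collapses a whole database into one deduplicated
#' sketch; \code{sketchIntersect()} and \code{sketchSubtract()} operate on
#' sketch pairs; \code{subtractDB()} subtracts one reference sketch (for
#' example, of a host or reference genome) from every member of a database,
#' yielding the "remainder sketches" that enrich variant-covering k-mers for
#' population-level clustering.  Inputs are never mutated.
#'
#' The result's occurrence-filter provenance is kept from the inputs, or
#' recorded as mixed (\code{NA}) when members differ; window totals do not
#' survive set algebra and are set to \code{NA}.
#'
#' @param x a [SketchDB-class] (\code{sketchUnion}) or [Sketch-class].
#' @param y a [Sketch-class].
#' @param db a [SketchDB-class].
#' @param ref a [Sketch-class] to subtract from every member.
#' @return a [Sketch-class], or a [SketchDB-class] for \code{subtractDB()}.
#' @name setops
#' @examples
#' sp <- shuffleSpace(2, a = 0, seed = 1)
#' p <- symmetricPattern(3, 1)
#' a <- sketchSequences("ACGTAC", p, sp, format = "seq")
#' b <- sketchSequences("CGTACG", p, sp, format = "seq")
#' sketchSize(sketchIntersect(a, b))
NULL

#' @rdname setops
#' @export
setMethod("sketchUnion", "SketchDB", function(x) {
  if (!length(x@sketches)) stop("parameter error: empty sketch database")
  codes <- sort(unique(unlist(lapply(x@sketches, function(s) s@codes))))
  .newOpSketch("union", codes, lapply(x@sketches, function(s) s@fingerprint))
})

#' @rdname setops
#' @export
setMethod("sketchIntersect", signature("Sketch", "Sketch"), function(x, y) {
  codes <- x@codes[!is.na(match(x@codes, y@codes))]
  .newOpSketch(paste0(x@sampleId, "&", y@sampleId), codes,
               list(x@fingerprint, y@fingerprint))
})

#' @rdname setops
#' @export
setMethod("sketchSubtract", signature("Sketch", "Sketch"), function(x, y) {
  codes <- x@codes[is.na(match(x@codes, y@codes))]
  .newOpSketch(x@sampleId, codes, list(x@fingerprint, y@fingerprint))
})

#' @rdname setops
#' @export
subtractDB <- function(db, ref) {
  stopifnot(is(db, "SketchDB"), is(ref, "Sketch"))
  if (!length(db@sketches)) stop("parameter error: empty sketch database")
  out <- lapply(db@sketches, sketchSubtract, y = ref)
  fp <- out[[1]]@fingerprint
  out <- lapply(out, function(s) { s@fingerprint <- fp; s })
  new("SketchDB", sketches = out, fingerprint = fp)
}
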