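#' @rdname patternWeight
#' @export
setGeneric("patternWeight", function(x) standardGeneric("patternWeight"))

#' @rdname spaceDim
#' @export
setGeneric("spaceDim", function(x) standardGeneric("spaceDim"))

#' @rdname recodeLength
#' @export
setGeneric("recodeLength", function(x, a) standardGeneric("recodeLength"))

#' @rdname reductionFold
#' @export
setGeneric("reductionFold", function(x) standardGeneric("reductionFold"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("sketchCodes", function(x) standardGeneric("sketchCodes"))

#' @rdname accessors
#' @export
setGeneric("sketchSize", function(x) standardGeneric("sketchSize"))

#' @rdname accessors
#' @export
setGeneric("kmerTotal", function(x) standardGeneric("kmerTotal"))

#' @rdname accessors
#' @export
setGeneric("fingerprint", function(x) standardGeneric("fingerprint"))

#' @rdname setops
#' @export
setGeneric("sketchUnion", function(x) standardGeneric("sketchUnion"))

#' @rdname setops
#' @export
setGeneric("sketchIntersect", function(x, y) standardGeneric("sketchIntersect"))

#' @rdname setops
#' @export
setGeneric("sketchSubtract", function(x, y) standardGeneric("sketchSubtract"))

#' @rdname exactJaccard
#' @export
setGeneric("exactJaccard", function(x, y) standardGeneric("exactJaccard"))

#' @rdname exactJaccard
#' @export
setGeneric("exactContainment", function(x, y) standardGeneric("exactContainment"))
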