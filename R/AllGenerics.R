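#' @rdname SamplingDesign
#' @param x,object a `SamplingDesign` (or other canopymr object as documented).
#' @export
setGeneric("occasions", function(x) standardGeneric("occasions"))

#' @rdname SamplingDesign
#' @export
setGeneric("studyTrees", function(x) standardGeneric("studyTrees"))

#' @rdname SamplingDesign
#' @export
setGeneric("heightLabels", function(x) standardGeneric("heightLabels"))

#' @rdname SamplingDesign
#' @export
setGeneric("nOccasions", function(x) standardGeneric("nOccasions"))

#' @rdname SamplingDesign
#' @export
setGeneric("nTrees", function(x) standardGeneric("nTrees"))

#' @rdname SamplingDesign
#' @export
setGeneric("nHeights", function(x) standardGeneric("nHeights"))

#' @rdname CaptureHistories
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))

#' @rdname CaptureHistories
#' @export
setGeneric("firstCapture", function(x) standardGeneric("firstCapture"))

#' @rdname CaptureHistories
#' @export
setGeneric("lastOccasion", function(x) standardGeneric("lastOccasion"))

#' @rdname CaptureHistories
#' @export
setGeneric("removedFlag", function(x) standardGeneric("removedFlag"))

#' @rdname CaptureHistories
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))

#' @rdname AbundanceTable
#' @export
setGeneric("newCounts", function(x) standardGeneric("newCounts"))

#' @rdname AbundanceTable
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))

#' @rdname MultistateParams
#' @export
setGeneric("survivalProb", function(x) standardGeneric("survivalProb"))

#' @rdname MultistateParams
#' @export
setGeneric("movementMatrix", function(x) standardGeneric("movementMatrix"))

#' @rdname MultistateParams
#' @export
setGeneric("recaptureProb", function(x) standardGeneric("recaptureProb"))

#' @rdname PosteriorDraws
#' @export
setGeneric("drawsMatrix", function(x) standardGeneric("drawsMatrix"))

#' @rdname PosteriorDraws
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))

#' @rdname PosteriorDraws
#' @export
setGeneric("pointwiseLogLik", function(x) standardGeneric("pointwiseLogLik"))

#' @rdname PosteriorDraws
#' @export
setGeneric("mcmcDiagnostics", function(x) standardGeneric("mcmcDiagnostics"))
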