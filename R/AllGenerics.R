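#' @include AllClasses.R
NULL

#' @rdname AreaGraph-accessors
#' @export
setGeneric("nAreas", function(x) standardGeneric("nAreas"))

#' @rdname AreaGraph-accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname AreaGraph-accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname AreaGraph-accessors
#' @export
setGeneric("degrees", function(x) standardGeneric("degrees"))

#' @rdname EdgeState-accessors
#' @export
setGeneric("retainedEdges", function(x) standardGeneric("retainedEdges"))

#' @rdname EdgeState-accessors
#' @export
setGeneric("removedEdges", function(x) standardGeneric("removedEdges"))

#' @rdname EdgeState-accessors
#' @export
setGeneric("wStar", function(x) standardGeneric("wStar"))

#' @rdname EdgeState-accessors
#' @export
setGeneric("stateIndex", function(x) standardGeneric("stateIndex"))

#' @rdname CandidatePath-accessors
#' @export
setGeneric("pathState", function(x, j) standardGeneric("pathState"))

#' @rdname CandidatePath-accessors
#' @export
setGeneric("pathLength", function(x) standardGeneric("pathLength"))

#' @rdname CandidatePath-accessors
#' @export
setGeneric("pathLogDets", function(x) standardGeneric("pathLogDets"))

#' @rdname CandidatePath-accessors
#' @export
setGeneric("removalOrder", function(x) standardGeneric("removalOrder"))
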