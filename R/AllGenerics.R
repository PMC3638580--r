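#' @rdname pathwayNodes
#' @export
setGeneric("pathwayNodes", function(x) standardGeneric("pathwayNodes"))

#' @rdname pathwayNodes
#' @export
setGeneric("pathwayEdges", function(x) standardGeneric("pathwayEdges"))

#' @rdname exitNodes
#' @export
setGeneric("exitNodes", function(x) standardGeneric("exitNodes"))

#' @rdname exitNodes
#' @export
setGeneric("exitNodes<-", function(x, value) standardGeneric("exitNodes<-"))

#' @rdname dockingScores
#' @export
setGeneric("dockingScores", function(x) standardGeneric("dockingScores"))

#' @rdname dockingScores
#' @export
setGeneric("referenceScores", function(x) standardGeneric("referenceScores"))

#' @rdname dockingScores
#' @export
setGeneric("compoundNames", function(x) standardGeneric("compoundNames"))

#' @rdname dockingScores
#' @export
setGeneric("targetNames", function(x) standardGeneric("targetNames"))

#' @rdname screeningMetrics
#' @export
setGeneric("screeningMetrics", function(x) standardGeneric("screeningMetrics"))

#' @rdname screeningMetrics
#' @export
setGeneric("screeningCorrelations",
           function(x) standardGeneric("screeningCorrelations"))
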