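#' Access the node and edge tables of a PathwayNetwork
#'
#' @param x a [PathwayNetwork].
#' @return `pathwayNodes()` returns the node `data.frame` (columns `id`,
#'   `label`, `kind`); `pathwayEdges()` the edge `data.frame` (columns
#'   `from`, `to`, `weight`).
#' @name pathwayNodes
#' @aliases pathwayEdges
#' @export
setMethod("pathwayNodes", "PathwayNetwork", function(x) x@nodes)

#' @rdname pathwayNodes
#' @export
setMethod("pathwayEdges", "PathwayNetwork", function(x) x@edges)

#' Get or set the explicit exit node set of a network
#'
#' Exit nodes are the terminal events of the pathway (the destination set of
#' network flux). An empty set means "auto-detect sinks"; see [detectExits()].
#'
#' @param x a [PathwayNetwork].
#' @param value character vector of node ids.
#' @return `exitNodes()` returns the explicitly declared exit ids (may be
#'   empty); the replacement form returns the modified network.
#' @name exitNodes
#' @export
setMethod("exitNodes", "PathwayNetwork", function(x) x@exitNodes)

#' @rdname exitNodes
#' @export
setMethod("exitNodes<-", "PathwayNetwork", function(x, value) {
    x@exitNodes <- as.character(value)
    validObject(x)
    x
})

#' Accessors for ScoreMatrix objects
#'
#' @param x a [ScoreMatrix].
#' @return `dockingScores()` the compound-by-target numeric matrix;
#'   `referenceScores()` the named per-target reference vector;
#'   `compoundNames()` / `targetNames()` the row/column ids.
#' @name dockingScores
#' @aliases referenceScores compoundNames targetNames
#' @export
setMethod("dockingScores", "ScoreMatrix", function(x) x@scores)

#' @rdname dockingScores
#' @export
setMethod("referenceScores", "ScoreMatrix",
          function(x) x@referenceScores[colnames(x@scores)])

#' @rdname dockingScores
#' @export
setMethod("compoundNames", "ScoreMatrix", function(x) rownames(x@scores))

#' @rdname dockingScores
#' @export
setMethod("targetNames", "ScoreMatrix", function(x) colnames(x@scores))

#' Accessors for ScreeningReport objects
#'
#' @param x a [ScreeningReport].
#' @return `screeningMetrics()` the per-compound metrics `data.frame`;
#'   `screeningCorrelations()` the accumulated correlation records.
#' @name screeningMetrics
#' @aliases screeningCorrelations
#' @export
setMethod("screeningMetrics", "ScreeningReport", function(x) x@metrics)

#' @rdname screeningMetrics
#' @export
setMethod("screeningCorrelations", "ScreeningReport",
          function(x) x@correlations)

setMethod("show", "PathwayNetwork", function(object) {
    cat(sprintf("PathwayNetwork: %d nodes, %d directed edges\n",
                nrow(object@nodes), nrow(object@edges)))
    tab <- table(object@nodes$kind)
    cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
    if (nrow(object@edges)) {
        w <- object@edges$weight
        cat(sprintf("  weights: [%g, %g] (floor %g, cap %g)\n",
                    min(w), max(w), object@weightFloor, object@weightCap))
    }
    if (length(object@exitNodes))
        cat("  exits:", paste(object@exitNodes, collapse = ", "), "\n")
    else
        cat("  exits: <auto-detect sinks>\n")
})

setMethod("show", "ScoreMatrix", function(object) {
    cat(sprintf("ScoreMatrix: %d compounds x %d targets\n",
                nrow(object@scores), ncol(object@scores)))
    cat("  targets:", paste(head(colnames(object@scores), 4), collapse = ", "),
        if (ncol(object@scores) > 4) "..." else "", "\n")
})

setMethod("show", "PerturbationProfile", function(object) {
    cat(sprintf("PerturbationProfile for '%s': %d target(s)\n",
                object@compound, length(object@edgeValues)))
    if (length(object@edgeValues)) {
        ev <- object@edgeValues
        cat(sprintf("  edge values in [%.3g, %.3g]\n", min(ev), max(ev)))
    }
})

setMethod("show", "ScreeningReport", function(object) {
    cat(sprintf("ScreeningReport: %d compound(s), ranked by %s\n",
                nrow(object@metrics), object@rankingKey))
    if (all(is.finite(object@baseline)))
        cat(sprintf("  baseline NE = %.4g, NF = %.4g\n",
                    object@baseline[["ne"]], object@baseline[["nf"]]))
    if (nrow(object@metrics)) {
        top <- head(object@metrics, 3)
        cat("  top:", paste(sprintf("%s (%.1f%%)", top$compound,
                                    top[[object@rankingKey]]),
                            collapse = ", "), "\n")
    }
    if (nrow(object@correlations))
        cat(sprintf("  %d correlation record(s)\n", nrow(object@correlations)))
})
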