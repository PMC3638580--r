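## S4 classes for the pathway-perturbation model.

NODE_KINDS <- c("protein", "small_molecule", "event")

#' PathwayNetwork: a directed, positively weighted signalling network
#'
#' A `PathwayNetwork` holds typed nodes (proteins, small molecules, terminal
#' events), directed weighted edges, and an optional explicit set of exit
#' nodes (the terminal biological event of the pathway, e.g. platelet
#' aggregation). Edge weights are dimensionless and constrained to
#' `[weightFloor, weightCap]`; the unperturbed network carries the initial
#' weight (default 10) on every edge.
#'
#' @slot nodes `data.frame` with columns `id` (unique, case-sensitive),
#'   `label`, `kind` (one of `"protein"`, `"small_molecule"`, `"event"`).
#' @slot edges `data.frame` with columns `from`, `to`, `weight`; directed
#'   `from -> to`, no self-loops, no duplicated pairs.
#' @slot exitNodes character vector of node ids; empty means "auto-detect
#'   sinks" (see [detectExits()]).
#' @slot weightFloor,weightCap numeric scalars bounding admissible weights.
#'
#' @param edges `data.frame` (or coercible) with columns `from` and `to` and
#'   optionally `weight`; missing weights are filled with `initialWeight`.
#' @param nodes optional node table; when `NULL` the nodes are inferred from
#'   the edge endpoints with `kind = "protein"`.
#' @param exitNodes character vector of designated exit node ids.
#' @param weightFloor,weightCap admissible weight range (defaults 10, 99999).
#' @param initialWeight weight assigned to edges lacking one (default 10).
#' @return A validated `PathwayNetwork` object.
#' @examples
#' net <- PathwayNetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
#' networkEfficiency(net)
#' @seealso [readPathwayNetwork()], [networkSummary()], [applyProfile()]
#' @aliases PathwayNetwork-class
#' @export
PathwayNetwork <- function(edges, nodes = NULL, exitNodes = character(),
                           weightFloor = 10, weightCap = 99999,
                           initialWeight = 10) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(edges)))
        stop("'edges' needs columns 'from' and 'to'")
    if (is.null(edges$weight))
        edges$weight <- rep(NA_real_, nrow(edges))
    edges$weight <- as.numeric(edges$weight)
    edges$weight[is.na(edges$weight)] <- initialWeight
    edges <- edges[, c("from", "to", "weight")]
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (is.null(nodes)) {
        ids <- unique(c(edges$from, edges$to))
        nodes <- data.frame(id = ids, label = ids,
                            kind = "protein", stringsAsFactors = FALSE)
    } else {
        nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
        if (is.null(nodes$id)) stop("'nodes' needs an 'id' column")
        nodes$id <- as.character(nodes$id)
        if (is.null(nodes$label)) nodes$label <- nodes$id
        if (is.null(nodes$kind)) nodes$kind <- "protein"
        nodes <- nodes[, c("id", "label", "kind")]
    }
    rownames(nodes) <- NULL
    rownames(edges) <- NULL
    new("PathwayNetwork", nodes = nodes, edges = edges,
        exitNodes = as.character(exitNodes),
        weightFloor = as.numeric(weightFloor),
        weightCap = as.numeric(weightCap))
}

setClass("PathwayNetwork",
    representation(nodes = "data.frame", edges = "data.frame",
                   exitNodes = "character",
                   weightFloor = "numeric", weightCap = "numeric"),
    prototype(exitNodes = character(), weightFloor = 10, weightCap = 99999))

setValidity("PathwayNetwork", function(object) {
    msg <- character()
    nd <- object@nodes; ed <- object@edges
    if (!all(c("id", "label", "kind") %in% names(nd)))
        return("'nodes' must have columns id, label, kind")
    if (!all(c("from", "to", "weight") %in% names(ed)))
        return("'edges' must have columns from, to, weight")
    if (anyDuplicated(nd$id))
        msg <- c(msg, "node ids must be unique")
    if (!all(nd$kind %in% NODE_KINDS))
        msg <- c(msg, sprintf("node kind must be one of %s",
                              paste(NODE_KINDS, collapse = ", ")))
    unknown <- setdiff(unique(c(ed$from, ed$to)), nd$id)
    if (length(unknown))
        msg <- c(msg, sprintf("edge endpoint(s) not declared as nodes: %s",
                              paste(unknown, collapse = ", ")))
    if (any(ed$from == ed$to))
        msg <- c(msg, sprintf("self-loop(s) not allowed: %s",
                 paste(unique(ed$from[ed$from == ed$to]), collapse = ", ")))
    if (anyDuplicated(paste(ed$from, ed$to, sep = "\r")))
        msg <- c(msg, "duplicate (from,to) edge pairs not allowed")
    if (nrow(ed)) {
        if (any(!is.finite(ed$weight)))
            msg <- c(msg, "edge weights must be finite")
        else {
            if (any(ed$weight < object@weightFloor))
                msg <- c(msg, sprintf("edge weight below floor %g",
                                      object@weightFloor))
            if (any(ed$weight > object@weightCap))
                msg <- c(msg, sprintf("edge weight above cap %g",
                                      object@weightCap))
        }
    }
    bad <- setdiff(object@exitNodes, nd$id)
    if (length(bad))
        msg <- c(msg, sprintf("exit node(s) not in network: %s",
                              paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' ScoreMatrix: compound-by-target docking scores with reference anchors
#'
#' Holds the docking score of each compound against each pathway target,
#' together with the per-target score of the reference ligand (the
#' co-crystallised ligand or a known inhibitor) that anchors the edge-value
#' transform. Higher scores mean stronger predicted binding.
#'
#' @slot scores numeric matrix, rows = compounds, columns = targets.
#' @slot referenceScores named numeric vector, strictly positive, one entry
#'   per target (names match `colnames(scores)`).
#'
#' @param scores numeric matrix with compound rownames and target colnames.
#' @param referenceScores named positive numeric vector covering every target.
#' @return A validated `ScoreMatrix`.
#' @examples
#' sm <- ScoreMatrix(matrix(5, 1, 1, dimnames = list("cmpd", "Thrombin")),
#'                   c(Thrombin = 5.02))
#' dockingScores(sm)
#' @aliases ScoreMatrix-class
#' @export
ScoreMatrix <- function(scores, referenceScores) {
    scores <- as.matrix(scores)
    storage.mode(scores) <- "double"
    new("ScoreMatrix", scores = scores,
        referenceScores = unlist(referenceScores))
}

setClass("ScoreMatrix",
    representation(scores = "matrix", referenceScores = "numeric"))

setValidity("ScoreMatrix", function(object) {
    msg <- character()
    sc <- object@scores; rf <- object@referenceScores
    if (is.null(rownames(sc)) || is.null(colnames(sc)))
        return("scores matrix needs compound rownames and target colnames")
    if (anyDuplicated(rownames(sc)))
        msg <- c(msg, "compound ids must be unique")
    if (anyDuplicated(colnames(sc)))
        msg <- c(msg, "target ids must be unique")
    if (is.null(names(rf)))
        return("referenceScores must be named by target")
    missing <- setdiff(colnames(sc), names(rf))
    if (length(missing))
        msg <- c(msg, sprintf("no reference score for target(s): %s",
                              paste(missing, collapse = ", ")))
    if (any(!is.finite(rf)) || any(rf <= 0))
        msg <- c(msg, "reference scores must be finite and strictly positive")
    if (length(msg)) msg else TRUE
})

#' PerturbationProfile: per-target edge values for one compound
#'
#' The edge value (EV) a compound imposes on every outgoing edge of each
#' docked target, as produced by [buildProfile()]. Values are clamped to
#' `[floor, cap]` (defaults 10 and 99999); larger values mean the target is
#' predicted to be more strongly inhibited.
#'
#' @slot compound single compound id.
#' @slot edgeValues named numeric vector, target id -> edge value.
#'
#' @param compound compound id (length-1 character).
#' @param edgeValues named numeric vector of edge values per target.
#' @return A validated `PerturbationProfile`.
#' @aliases PerturbationProfile-class
#' @export
PerturbationProfile <- function(compound, edgeValues) {
    new("PerturbationProfile", compound = as.character(compound),
        edgeValues = edgeValues)
}

setClass("PerturbationProfile",
    representation(compound = "character", edgeValues = "numeric"))

setValidity("PerturbationProfile", function(object) {
    msg <- character()
    if (length(object@compound) != 1L)
        msg <- c(msg, "'compound' must be a single id")
    ev <- object@edgeValues
    if (length(ev) && is.null(names(ev)))
        msg <- c(msg, "edgeValues must be named by target")
    if (any(!is.finite(ev)) || any(ev <= 0))
        msg <- c(msg, "edge values must be finite and positive")
    if (length(msg)) msg else TRUE
})

#' ScreeningReport: ranked compound metrics plus activity correlations
#'
#' Produced by [screenCompounds()] and augmented by [rankCompounds()] and
#' [correlateActivity()]. The metrics table has one row per compound with
#' NE, NF, their values relative to the unperturbed baseline (percent), the
#' percent decreases, and the combination score (geometric mean of the two
#' decreases).
#'
#' @slot metrics `data.frame` with columns `compound`, `ne`, `nf`,
#'   `ne_relative`, `nf_relative`, `ne_decrease`, `nf_decrease`,
#'   `combination`, ordered by the ranking key.
#' @slot rankingKey character, the metric the table is sorted by.
#' @slot correlations `data.frame` with columns `predictor`, `subset`, `n`,
#'   `r`, `slope`, `intercept` (possibly empty).
#' @slot baseline named numeric, baseline `ne` and `nf` of the unperturbed
#'   network.
#' @aliases ScreeningReport-class
#' @export
ScreeningReport <- function(metrics, rankingKey = "ne_decrease",
                            correlations = emptyCorrelations(),
                            baseline = c(ne = NA_real_, nf = NA_real_)) {
    new("ScreeningReport", metrics = metrics, rankingKey = rankingKey,
        correlations = correlations, baseline = baseline)
}

setClass("ScreeningReport",
    representation(metrics = "data.frame", rankingKey = "character",
                   correlations = "data.frame", baseline = "numeric"))

setValidity("ScreeningReport", function(object) {
    msg <- character()
    need <- c("compound", "ne", "nf", "ne_relative", "nf_relative",
              "ne_decrease", "nf_decrease", "combination")
    if (!all(need %in% names(object@metrics)))
        msg <- c(msg, sprintf("metrics must have columns: %s",
                              paste(need, collapse = ", ")))
    else if (anyDuplicated(object@metrics$compound))
        msg <- c(msg, "metrics compound ids must be unique")
    if (nrow(object@correlations) &&
        any(abs(object@correlations$r) > 1 + 1e-12))
        msg <- c(msg, "correlation r must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

emptyCorrelations <- function() {
    data.frame(predictor = character(), subset = character(),
               n = integer(), r = numeric(), slope = numeric(),
               intercept = numeric(), stringsAsFactors = FALSE)
}
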