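## Topological summaries of the unweighted network view.

#' Summarise the topology of a pathway network
#'
#' Computes node and edge counts, the average degree `2 * E / N` (in-degree
#' plus out-degree, averaged over nodes), and the average shortest path
#' length, defined as the mean directed hop count over ordered node pairs
#' with a finite distance. The path length is computed on the unweighted
#' view of the network: it describes the wiring, not the current edge
#' weights.
#'
#' @param net a [PathwayNetwork] with at least one node.
#' @return A list with components `nodeCount`, `edgeCount`, `averageDegree`
#'   and `averageShortestPathLength` (`NA` when no pair is connected).
#' @examples
#' net <- PathwayNetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
#' networkSummary(net)$averageDegree  # 2*2/3
#' @export
networkSummary <- function(net) {
    stopifnot(is(net, "PathwayNetwork"))
    n <- nrow(pathwayNodes(net))
    if (n < 1L) stop("network must have at least one node")
    e <- nrow(pathwayEdges(net))
    if (e == 0L)
        return(list(nodeCount = n, edgeCount = 0L, averageDegree = 0,
                    averageShortestPathLength = NA_real_))
    g <- asIgraph(net)
    hops <- igraph::distances(g, mode = "out", weights = NA)
    diag(hops) <- Inf                 # ordered pairs i != j only
    finite <- hops[is.finite(hops)]
    list(nodeCount = n,
         edgeCount = e,
         averageDegree = 2 * e / n,
         averageShortestPathLength =
             if (length(finite)) mean(finite) else NA_real_)
}

#' Determine the exit node set of a network
#'
#' Returns the explicitly declared exit nodes when the network has any;
#' otherwise auto-detects the sinks (nodes with out-degree 0), which in a
#' signalling pathway correspond to the terminal event. A network with
#' neither explicit exits nor sinks (for example a cycle) is a configuration
#' error: declare exits via [`exitNodes<-`] or a `%exit` directive.
#'
#' @param net a [PathwayNetwork].
#' @return Character vector of exit node ids.
#' @examples
#' net <- PathwayNetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
#' detectExits(net)  # "C"
#' @export
detectExits <- function(net) {
    stopifnot(is(net, "PathwayNetwork"))
    if (length(exitNodes(net)))
        return(exitNodes(net))
    ids <- pathwayNodes(net)$id
    sinks <- ids[!(ids %in% pathwayEdges(net)$from)]
    if (!length(sinks))
        stop("network has no sink and no explicit exit set; ",
             "declare exits with exitNodes(net) <- ... or a %exit directive")
    sinks
}

## internal: igraph view preserving node order and edge weights
asIgraph <- function(net) {
    nd <- pathwayNodes(net)
    igraph::graph_from_data_frame(
        pathwayEdges(net), directed = TRUE,
        vertices = data.frame(name = nd$id, stringsAsFactors = FALSE))
}
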