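## Network efficiency, network flux and derived compound metrics.

#' All-pairs weighted shortest path lengths
#'
#' Directed shortest-path lengths between every ordered node pair, following
#' edge direction and minimising total edge weight (Dijkstra; all weights
#' are positive by construction). Unreachable pairs are `Inf`; the diagonal
#' is `NA` since a node's distance to itself is excluded from every metric.
#'
#' @param net a [PathwayNetwork].
#' @return Numeric matrix with node ids as dimnames.
#' @examples
#' net <- PathwayNetwork(data.frame(from = c("A", "B", "A"),
#'                                  to = c("B", "C", "C"),
#'                                  weight = c(10, 10, 30)))
#' shortestPathLengths(net)["A", "C"]  # 20, via B
#' @export
shortestPathLengths <- function(net) {
    stopifnot(is(net, "PathwayNetwork"))
    edges <- pathwayEdges(net)
    if (nrow(edges) && any(edges$weight <= 0))
        stop("all edge weights must be strictly positive")
    n <- nrow(pathwayNodes(net))
    if (n <= 1L || nrow(edges) == 0L) {
        d <- matrix(Inf, n, n,
                    dimnames = list(pathwayNodes(net)$id,
                                    pathwayNodes(net)$id))
        diag(d) <- NA_real_
        return(d)
    }
    g <- asIgraph(net)
    d <- igraph::distances(g, mode = "out",
                           weights = igraph::E(g)$weight,
                           algorithm = "dijkstra")
    diag(d) <- NA_real_
    d
}

#' Network efficiency
#'
#' The sum of reciprocal weighted shortest-path lengths over node pairs,
#' with unreachable pairs contributing 0. `pairMode = "ordered"` (the
#' default) sums over all ordered pairs `(i, j)`, `i != j`, following edge
#' direction; `"unordered"` sums one term per unordered pair using the
#' smaller of the two directed distances.
#'
#' @param net a [PathwayNetwork].
#' @param pairMode `"ordered"` or `"unordered"`.
#' @return Nonnegative scalar.
#' @examples
#' net <- PathwayNetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
#' networkEfficiency(net)  # 1/10 + 1/10 + 1/20 = 0.25
#' @export
networkEfficiency <- function(net, pairMode = c("ordered", "unordered")) {
    pairMode <- match.arg(pairMode)
    d <- shortestPathLengths(net)
    if (pairMode == "unordered" && nrow(d) > 1L)
        d <- pmin(d, t(d))
    inv <- 1 / d
    inv[!is.finite(inv) | is.na(inv)] <- 0
    diag(inv) <- 0
    if (pairMode == "unordered")
        inv[lower.tri(inv, diag = TRUE)] <- 0
    sum(inv)
}

#' Network flux
#'
#' The restriction of [networkEfficiency()] to ordered pairs whose
#' destination is an exit node: the sum of `1/d(i, j)` over all `i != j`
#' with `j` in `exits`, unreachable pairs contributing 0. Flux emphasises
#' impact on signal actually arriving at the pathway's terminal event.
#'
#' @param net a [PathwayNetwork].
#' @param exits exit node ids; default [detectExits()].
#' @return Nonnegative scalar, never exceeding the network efficiency.
#' @examples
#' net <- PathwayNetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
#' networkFlux(net)  # 1/20 + 1/10 = 0.15 into exit C
#' @export
networkFlux <- function(net, exits = NULL) {
    if (is.null(exits)) exits <- detectExits(net)
    if (!length(exits)) stop("exit set must not be empty")
    missing <- setdiff(exits, pathwayNodes(net)$id)
    if (length(missing))
        stop("exit node(s) not in network: ", paste(missing, collapse = ", "))
    d <- shortestPathLengths(net)
    inv <- 1 / d[, exits, drop = FALSE]
    inv[!is.finite(inv) | is.na(inv)] <- 0
    sum(inv)
}

#' Percent decrease relative to a baseline
#'
#' `100 * (baseline - perturbed) / baseline`. The unperturbed network is
#' taken as 100%, so a perturbed metric at half the baseline is a 50%
#' decrease. Negative values (the metric rose) are reported as-is.
#'
#' @param baseline strictly positive baseline value.
#' @param perturbed nonnegative perturbed value.
#' @return Percent decrease (vectorised).
#' @export
relativeDecrease <- function(baseline, perturbed) {
    if (any(!is.finite(baseline)) || any(baseline <= 0))
        stop("baseline must be finite and strictly positive")
    100 * (baseline - perturbed) / baseline
}

#' Combination score of NE and NF decreases
#'
#' The geometric mean of the percent decreases of network efficiency and
#' network flux, `sqrt(ne_decrease * nf_decrease)`. Negative decreases are
#' clamped to 0 before the product so the square root is defined; the score
#' is symmetric in its arguments and lies between them.
#'
#' @param neDecrease,nfDecrease percent decreases (vectorised).
#' @return Percent-scale combination score.
#' @examples
#' combinationScore(39.9, 61.5)  # ~49.5
#' @export
combinationScore <- function(neDecrease, nfDecrease) {
    sqrt(pmax(neDecrease, 0) * pmax(nfDecrease, 0))
}

#' Score every compound of a ScoreMatrix against a pathway network
#'
#' Runs the full perturbation pipeline: for each compound, build its
#' perturbation profile ([buildProfile()]), reweight the baseline network
#' ([applyProfile()]), and compute network efficiency and flux, their values
#' relative to the unperturbed baseline (percent), the percent decreases,
#' and the combination score. The baseline network has every edge at
#' `initialWeight`; profile targets must all be nodes of the network.
#'
#' @param net a [PathwayNetwork] (weights are reset to `initialWeight` for
#'   the baseline).
#' @param scores a [ScoreMatrix].
#' @param exits exit node ids; default [detectExits()].
#' @param constant,floor,cap edge-value transform parameters, see
#'   [edgeValue()].
#' @param initialWeight baseline weight of every edge (default 10).
#' @param pairMode passed to [networkEfficiency()].
#' @param rankingKey metric to sort the report by (`"ne_decrease"`,
#'   `"nf_decrease"` or `"combination"`).
#' @return A [ScreeningReport]; see [screeningMetrics()].
#' @examples
#' net <- generatePathwayNetwork(nodeCount = 16, edgeCount = 24, seed = 1)
#' sm <- generateScores(net, nCompounds = 3,
#'                      planted = list(c1 = list(targets = "N1", potency = 1)),
#'                      seed = 1)
#' screenCompounds(net, sm)
#' @export
screenCompounds <- function(net, scores, exits = NULL, constant = 2.30,
                            floor = 10, cap = 99999, initialWeight = 10,
                            pairMode = c("ordered", "unordered"),
                            rankingKey = "ne_decrease") {
    stopifnot(is(net, "PathwayNetwork"), is(scores, "ScoreMatrix"))
    pairMode <- match.arg(pairMode)
    base <- net
    base@edges$weight <- rep(initialWeight, nrow(base@edges))
    validObject(base)
    if (is.null(exits)) exits <- detectExits(base)
    baseNE <- networkEfficiency(base, pairMode)
    baseNF <- networkFlux(base, exits)
    if (baseNE <= 0 || baseNF <= 0)
        stop("baseline NE and NF must be positive; ",
             "check connectivity and the exit set")
    compounds <- compoundNames(scores)
    rows <- lapply(compounds, function(cmpd) {
        prof <- buildProfile(scores, cmpd, constant = constant,
                             floor = floor, cap = cap)
        pert <- applyProfile(base, prof)
        ne <- networkEfficiency(pert, pairMode)
        nf <- networkFlux(pert, exits)
        data.frame(compound = cmpd, ne = ne, nf = nf,
                   ne_relative = 100 * ne / baseNE,
                   nf_relative = 100 * nf / baseNF,
                   ne_decrease = relativeDecrease(baseNE, ne),
                   nf_decrease = relativeDecrease(baseNF, nf),
                   stringsAsFactors = FALSE)
    })
    metrics <- do.call(rbind, rows)
    metrics$combination <- combinationScore(metrics$ne_decrease,
                                            metrics$nf_decrease)
    report <- ScreeningReport(metrics, rankingKey = rankingKey,
                              baseline = c(ne = baseNE, nf = baseNF))
    rankCompounds(report, key = rankingKey)
}
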