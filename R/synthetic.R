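## Seeded generators for pathway-like networks and docking-score matrices,
## plus the bundled data fixtures.

#' Generate a scale-free-like directed pathway network
#'
#' Builds a layered receptor -> intermediate -> exit scaffold and then adds
#' edges by out-preferential attachment, emulating the statistical structure
#' of a signalling pathway: a few designated receptor sources, a terminal
#' exit layer of sinks, heavy-tailed in-degrees, and every node on some
#' receptor-to-exit path. Edges always point from an earlier to a later node
#' in the layer order, so the network is acyclic, receptors have no incoming
#' edges and exits no outgoing ones. The default sizes (64 nodes, 91 edges,
#' average degree 2.84) match the curated platelet-aggregation pathway.
#'
#' The generator is a pure function of its arguments: the same seed yields a
#' byte-identical network, and the caller's random-number state is left
#' untouched.
#'
#' @param nodeCount,edgeCount total nodes and directed edges
#'   (`edgeCount >= nodeCount - 1`).
#' @param receptorCount number of source-layer receptor nodes.
#' @param exitCount number of terminal sink nodes (declared as exits).
#' @param attachmentBias exponent on `in-degree + 1` when choosing targets
#'   for the extra edges; larger values give heavier-tailed in-degrees.
#' @param seed integer seed.
#' @return A [PathwayNetwork] with node ids `R1..`, `N1..`, `EXIT1..`.
#' @examples
#' net <- generatePathwayNetwork(seed = 42)
#' networkSummary(net)$averageDegree  # 2 * 91 / 64
#' @export
generatePathwayNetwork <- function(nodeCount = 64, edgeCount = 91,
                                   receptorCount = 6, exitCount = 1,
                                   attachmentBias = 1, seed = 1) {
    if (receptorCount < 1L || exitCount < 1L)
        stop("need at least one receptor and one exit")
    if (receptorCount + exitCount >= nodeCount)
        stop("receptorCount + exitCount must be smaller than nodeCount")
    if (edgeCount < nodeCount - 1L)
        stop("edgeCount must be at least nodeCount - 1")
    if (attachmentBias <= 0) stop("attachmentBias must be positive")
    n <- nodeCount
    nInter <- n - receptorCount - exitCount
    ids <- c(paste0("R", seq_len(receptorCount)),
             paste0("N", seq_len(nInter)),
             paste0("EXIT", seq_len(exitCount)))
    isReceptor <- seq_len(n) <= receptorCount
    isExit <- seq_len(n) > receptorCount + nInter
    ## max edges under earlier->later, source non-exit, target non-receptor
    maxEdges <- sum(vapply(which(!isExit), function(v)
        sum(!isReceptor & seq_len(n) > v), integer(1)))
    if (edgeCount > maxEdges)
        stop("edgeCount too large for an acyclic layered network of this size")
    withSeed(seed, {
        from <- integer(0); to <- integer(0)
        key <- character(0)
        addEdge <- function(u, v) {
            from <<- c(from, u); to <<- c(to, v)
            key <<- c(key, paste(u, v))
        }
        ## every non-receptor gets an in-edge from an earlier non-exit node,
        ## so every node is reachable from the receptor layer; preferring
        ## parents that still lack an out-edge keeps the scaffold within the
        ## nodeCount - 1 edge budget
        for (v in which(!isReceptor)) {
            cand <- which(!isExit & seq_len(n) < v)
            fresh <- cand[!cand %in% from]
            addEdge(resample(if (length(fresh)) fresh else cand, 1L), v)
        }
        ## every non-exit node with no outgoing edge gets one to a later
        ## non-receptor node, so every node reaches the exit layer
        for (v in which(!isExit)) {
            if (!v %in% from) {
                cand <- which(!isReceptor & seq_len(n) > v)
                cand <- cand[!paste(v, cand) %in% key]
                addEdge(v, resample(cand, 1L))
            }
        }
        if (length(from) > edgeCount)
            stop("edgeCount too small for the reachability scaffold; ",
                 "increase edgeCount or reduce receptorCount/exitCount")
        ## top up by out-preferential attachment on in-degree
        guard <- 0L
        while (length(from) < edgeCount) {
            guard <- guard + 1L
            if (guard > 50L * edgeCount)
                stop("could not place all edges; counts look infeasible")
            u <- resample(which(!isExit), 1L)
            cand <- which(!isReceptor & seq_len(n) > u)
            cand <- cand[!paste(u, cand) %in% key]
            if (!length(cand)) next
            indeg <- tabulate(to, nbins = n)
            addEdge(u, resample(cand, 1L,
                                prob = (indeg[cand] + 1)^attachmentBias))
        }
        edges <- data.frame(from = ids[from], to = ids[to], weight = 10,
                            stringsAsFactors = FALSE)
        edges <- edges[order(match(edges$from, ids), match(edges$to, ids)), ]
        rownames(edges) <- NULL
        nodes <- data.frame(id = ids, label = ids,
                            kind = ifelse(isExit, "event", "protein"),
                            stringsAsFactors = FALSE)
        PathwayNetwork(edges, nodes = nodes, exitNodes = ids[isExit])
    })
}

#' Generate a docking-score matrix with planted actives
#'
#' Produces a compound-by-target [ScoreMatrix] for a network: every cell is
#' Gaussian noise (sd `scoreNoiseSd`, floored at 0), and each planted
#' compound additionally scores `potency * referenceScore` on its planted
#' targets. With zero noise, a potency-1 compound therefore docks exactly
#' as well as the reference ligand, and a potency-0 compound not at all.
#'
#' @param net a [PathwayNetwork]; all targets must be nodes of it.
#' @param nCompounds number of compounds (at least `length(planted)`);
#'   unplanted compounds are named `compound01`, `compound02`, ...
#' @param planted named list, compound id -> `list(targets = <ids>,
#'   potency = <fraction in [0, 1]>)`.
#' @param targets target panel; default the union of planted targets.
#' @param referenceScores named positive vector for the panel; default
#'   sampled (seeded) from the bundled nineteen-target reference table.
#' @param scoreNoiseSd standard deviation of the additive score noise.
#' @param seed integer seed; identical arguments give identical matrices.
#' @return A [ScoreMatrix].
#' @export
generateScores <- function(net, nCompounds, planted = list(),
                           targets = NULL, referenceScores = NULL,
                           scoreNoiseSd = 0, seed = 1) {
    stopifnot(is(net, "PathwayNetwork"))
    if (scoreNoiseSd < 0) stop("scoreNoiseSd must be nonnegative")
    plantedTargets <- unique(unlist(lapply(planted, `[[`, "targets")))
    if (is.null(targets)) targets <- plantedTargets
    if (!length(targets))
        stop("no targets: supply 'targets' or a nonempty 'planted' list")
    ids <- pathwayNodes(net)$id
    missing <- setdiff(c(targets, plantedTargets), ids)
    if (length(missing))
        stop("target(s) not in network: ", paste(missing, collapse = ", "))
    if (nCompounds < length(planted))
        stop("nCompounds smaller than the number of planted compounds")
    withSeed(seed, {
        if (is.null(referenceScores)) {
            pool <- loadFixture("targets_table1")$score
            referenceScores <- setNames(
                sample(pool, length(targets), replace = TRUE), targets)
        }
        compounds <- c(names(planted),
                       sprintf("compound%02d",
                               seq_len(nCompounds - length(planted))))
        m <- matrix(0, nCompounds, length(targets),
                    dimnames = list(compounds, targets))
        for (cmpd in names(planted)) {
            p <- planted[[cmpd]]
            if (p$potency < 0 || p$potency > 1)
                stop("planted potency must lie in [0, 1]")
            m[cmpd, p$targets] <- p$potency * referenceScores[p$targets]
        }
        if (scoreNoiseSd > 0)
            m <- m + rnorm(length(m), sd = scoreNoiseSd)
        m <- pmax(m, 0)
        ScoreMatrix(m, referenceScores)
    })
}

#' Load a bundled data fixture
#'
#' Three fixtures ship with the package:
#' \describe{
#'   \item{`targets_table1`}{The nineteen platelet-pathway docking targets
#'     with UniProt/PDB annotations and the docking score of each target's
#'     reference ligand (e.g. thrombin 5.02, adenylate cyclase 6.38).}
#'   \item{`compounds_table2`}{Twenty-one compounds (nineteen natural
#'     products plus the drugs tirofiban and dipyridamole) with experimental
#'     whole-blood antiplatelet inhibition at 34 uM, published NE/NF percent
#'     decreases, the published combination column, glycoside/drug flags,
#'     and `combination_recomputed` (the geometric-mean formula applied to
#'     the published decreases; a few published cells differ from the
#'     formula).}
#'   \item{`platelet_network`}{A curated, synthetic approximation of the
#'     platelet-aggregation pathway with 64 nodes and 91 directed edges,
#'     exit node \dQuote{Platelet aggregation}, containing all nineteen
#'     targets. The wiring is reconstructed from public pathway knowledge
#'     and is not an exact copy of any published diagram.}
#' }
#'
#' @param name fixture name.
#' @return A `data.frame` for the two tables, a [PathwayNetwork] for the
#'   network.
#' @examples
#' nrow(loadFixture("compounds_table2"))  # 21
#' @export
loadFixture <- function(name = c("targets_table1", "compounds_table2",
                                 "platelet_network")) {
    name <- match.arg(name)
    path <- function(f) system.file("extdata", f, package = "pathflux",
                                    mustWork = TRUE)
    switch(name,
        targets_table1 = read.csv(path("targets_table1.csv"),
                                  check.names = FALSE,
                                  stringsAsFactors = FALSE),
        compounds_table2 = {
            df <- readActivityTable(path("compounds_table2.csv"))
            df$combination_recomputed <-
                combinationScore(df$ne_decrease, df$nf_decrease)
            df
        },
        platelet_network =
            readPathwayNetwork(path("platelet_network_curated.tsv"),
                               format = "tsv"))
}

## run code under a fixed seed without disturbing the caller's RNG state
withSeed <- function(seed, code) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    code
}

## sample() that never treats a length-1 x as 1:x
resample <- function(x, size, prob = NULL) {
    x[sample.int(length(x), size, prob = prob)]
}
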