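# Independent brute-force oracle: Floyd-Warshall all-pairs shortest paths
# in plain R, plus NE/NF by direct summation over the distance matrix.
# Deliberately shares no code with the package's Dijkstra-based path.

oracleDistances <- function(net) {
    ids <- pathwayNodes(net)$id
    n <- length(ids)
    d <- matrix(Inf, n, n, dimnames = list(ids, ids))
    diag(d) <- 0
    ed <- pathwayEdges(net)
    for (k in seq_len(nrow(ed)))
        d[ed$from[k], ed$to[k]] <- min(d[ed$from[k], ed$to[k]], ed$weight[k])
    for (k in seq_len(n))
        for (i in seq_len(n))
            for (j in seq_len(n))
                if (d[i, k] + d[k, j] < d[i, j])
                    d[i, j] <- d[i, k] + d[k, j]
    diag(d) <- NA_real_
    d
}

oracleNE <- function(net) {
    d <- oracleDistances(net)
    s <- 0
    for (i in seq_len(nrow(d)))
        for (j in seq_len(ncol(d)))
            if (i != j && is.finite(d[i, j]))
                s <- s + 1 / d[i, j]
    s
}

oracleNF <- function(net, exits) {
    d <- oracleDistances(net)
    ids <- rownames(d)
    s <- 0
    for (i in seq_len(nrow(d)))
        for (j in which(ids %in% exits))
            if (i != j && is.finite(d[i, j]))
                s <- s + 1 / d[i, j]
    s
}

# Random weighted digraph on <= nMax nodes (no self-loops, no duplicate
# ordered pairs); may be disconnected, may contain cycles.
randomDigraph <- function(seed, nMax = 12) {
    set.seed(seed)
    n <- sample(2:nMax, 1)
    ids <- paste0("v", seq_len(n))
    pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    m <- sample(seq_len(nrow(pairs)), sample(seq_len(nrow(pairs)), 1))
    edges <- pairs[m, ]
    edges$weight <- round(runif(nrow(edges), 10, 500), 2)
    nodes <- data.frame(id = ids, label = ids, kind = "protein",
                        stringsAsFactors = FALSE)
    PathwayNetwork(edges, nodes = nodes)
}

# tiny three-node directed path A -> B -> C with unit baseline weights
tinyPath <- function(w = c(10, 10)) {
    PathwayNetwork(data.frame(from = c("A", "B"), to = c("B", "C"),
                              weight = w))
}
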