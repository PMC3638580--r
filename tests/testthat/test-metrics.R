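test_that("weighted shortest paths follow edge direction and weights", {
    net <- PathwayNetwork(data.frame(from = c("A", "B", "A"),
                                     to = c("B", "C", "C"),
                                     weight = c(10, 10, 30)))
    d <- shortestPathLengths(net)
    expect_equal(d["A", "C"], 20)  # via B, not the direct 30 edge
    expect_equal(d["A", "B"], 10)
    expect_true(is.infinite(d["C", "A"]))  # direction matters
    expect_true(is.na(d["A", "A"]))
    single <- PathwayNetwork(data.frame(from = character(),
                                        to = character()),
                             nodes = data.frame(id = "A"))
    expect_true(all(is.na(shortestPathLengths(single))))
})

test_that("paths, NE and NF match the brute-force oracle on random digraphs", {
    for (seed in 1:100) {
        net <- randomDigraph(seed)
        d <- shortestPathLengths(net)
        expect_equal(d, oracleDistances(net), tolerance = 1e-9,
                     label = paste("seed", seed))
        expect_equal(networkEfficiency(net), oracleNE(net),
                     tolerance = 1e-9, label = paste("NE seed", seed))
        exits <- pathwayNodes(net)$id[1:2]
        expect_equal(networkFlux(net, exits), oracleNF(net, exits),
                     tolerance = 1e-9, label = paste("NF seed", seed))
    }
})

test_that("NE agrees with hand enumeration and the path closed form", {
    # A->B->C at weight 10: 1/10 + 1/10 + 1/20
    expect_equal(networkEfficiency(tinyPath()), 0.25)
    # directed path of n nodes, weight w: sum_k (n-k)/(k w)
    for (n in 2:8) {
        w <- 10
        ids <- paste0("p", seq_len(n))
        net <- PathwayNetwork(data.frame(from = ids[-n], to = ids[-1],
                                         weight = w))
        k <- seq_len(n - 1)
        expect_equal(networkEfficiency(net), sum((n - k) / (k * w)),
                     tolerance = 1e-12)
    }
    empty <- PathwayNetwork(data.frame(from = character(), to = character()),
                            nodes = data.frame(id = c("A", "B")))
    expect_equal(networkEfficiency(empty), 0)
})

test_that("NF sums only paths into the exit set and never exceeds NE", {
    p3 <- tinyPath()
    expect_equal(networkFlux(p3, "C"), 1 / 20 + 1 / 10)
    # exits = all nodes reduces NF to NE
    ids <- pathwayNodes(p3)$id
    expect_equal(networkFlux(p3, ids), networkEfficiency(p3))
    # exit with no incoming paths contributes nothing
    iso <- PathwayNetwork(data.frame(from = "A", to = "B"),
                          nodes = data.frame(id = c("A", "B", "Z")))
    expect_equal(networkFlux(iso, "Z"), 0)
    expect_error(networkFlux(p3, character()), "empty")
    expect_error(networkFlux(p3, "nope"), "not in network")
    for (seed in 1:25) {
        net <- randomDigraph(seed + 200)
        exits <- sample(pathwayNodes(net)$id, 2)
        expect_lte(networkFlux(net, exits),
                   networkEfficiency(net) + 1e-12)
    }
})

test_that("raising any single edge weight never increases NE or NF", {
    for (seed in 1:15) {
        net <- randomDigraph(seed + 400)
        exits <- pathwayNodes(net)$id[1]
        ne0 <- networkEfficiency(net)
        nf0 <- networkFlux(net, exits)
        ed <- pathwayEdges(net)
        for (k in sample(nrow(ed), min(4, nrow(ed)))) {
            up <- net
            up@edges$weight[k] <- up@edges$weight[k] * 50
            expect_lte(networkEfficiency(up), ne0 + 1e-12)
            expect_lte(networkFlux(up, exits), nf0 + 1e-12)
            # and decreasing back toward the floor never hurts
            down <- net
            down@edges$weight[k] <- 10
            expect_gte(networkEfficiency(down), ne0 - 1e-12)
        }
    }
})

test_that("unordered pair mode counts each pair once", {
    # 2-cycle: ordered sums both directions, unordered the shorter one
    cyc <- PathwayNetwork(data.frame(from = c("A", "B"), to = c("B", "A"),
                                     weight = c(10, 40)))
    expect_equal(networkEfficiency(cyc), 1 / 10 + 1 / 40)
    expect_equal(networkEfficiency(cyc, pairMode = "unordered"), 1 / 10)
    # on a DAG every unordered pair is reachable in at most one direction,
    # so the two conventions coincide
    dag <- generatePathwayNetwork(nodeCount = 20, edgeCount = 30,
                                  receptorCount = 3, seed = 9)
    expect_equal(networkEfficiency(dag, pairMode = "unordered"),
                 networkEfficiency(dag))
})

test_that("relative decrease is percent of baseline", {
    expect_equal(relativeDecrease(5, 5), 0)
    expect_equal(relativeDecrease(10, 5), 50)
    expect_equal(relativeDecrease(48.496, 8.849), 81.75259, tolerance = 1e-5)
    expect_error(relativeDecrease(0, 1), "positive")
    expect_error(relativeDecrease(-3, 1), "positive")
})

test_that("combination score is the geometric mean with negative clamping", {
    expect_equal(round(combinationScore(39.9, 61.5), 1), 49.5)
    expect_equal(round(combinationScore(33.2, 50.9), 1), 41.1)
    # symmetric, idempotent on the diagonal, between min and max
    set.seed(1)
    a <- runif(50, 0, 100); b <- runif(50, 0, 100)
    expect_equal(combinationScore(a, b), combinationScore(b, a))
    expect_equal(combinationScore(a, a), a)
    expect_true(all(combinationScore(a, b) >= pmin(a, b) - 1e-12))
    expect_true(all(combinationScore(a, b) <= pmax(a, b) + 1e-12))
    # negative decreases clamp to zero inside the score only
    expect_equal(combinationScore(-5, 80), 0)
})

test_that("screening pipeline reports baseline-relative metrics", {
    net <- generatePathwayNetwork(nodeCount = 20, edgeCount = 32,
                                  receptorCount = 3, seed = 21)
    m <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE,
                dimnames = list(c("inert", "hit"), c("N1", "N2")))
    sm <- ScoreMatrix(m, c(N1 = 5, N2 = 5))
    rpt <- screenCompounds(net, sm)
    tab <- screeningMetrics(rpt)
    inert <- tab[tab$compound == "inert", ]
    # baseline network: relative NE = 100%, decreases 0, combination 0
    expect_equal(inert$ne_relative, 100)
    expect_equal(inert$nf_relative, 100)
    expect_equal(inert$ne_decrease, 0)
    expect_equal(inert$combination, 0)
    hit <- tab[tab$compound == "hit", ]
    expect_gt(hit$ne_decrease, 0)
    expect_gt(hit$nf_decrease, 0)
    expect_true(all(tab$nf <= tab$ne + 1e-12))
    expect_equal(tab$ne_relative + tab$ne_decrease, rep(100, 2))
    expect_equal(tab$nf_relative + tab$nf_decrease, rep(100, 2))
    # ranked by ne_decrease: the hit comes first
    expect_equal(tab$compound, c("hit", "inert"))
})
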