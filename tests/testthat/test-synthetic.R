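test_that("network generator is deterministic and leaves RNG state alone", {
    a <- generatePathwayNetwork(seed = 42)
    b <- generatePathwayNetwork(seed = 42)
    expect_identical(pathwayEdges(a), pathwayEdges(b))
    expect_identical(pathwayNodes(a), pathwayNodes(b))
    set.seed(123); before <- rnorm(3)
    set.seed(123); invisible(generatePathwayNetwork(seed = 7))
    expect_identical(rnorm(3), before)
    expect_false(identical(pathwayEdges(a),
                           pathwayEdges(generatePathwayNetwork(seed = 43))))
})

test_that("generated networks honour counts, layering and reachability", {
    net <- generatePathwayNetwork(nodeCount = 64, edgeCount = 91, seed = 1)
    s <- networkSummary(net)
    expect_equal(s$nodeCount, 64L)
    expect_equal(s$edgeCount, 91L)
    expect_equal(round(s$averageDegree, 2), 2.84)
    for (seed in 1:10) {
        n <- sample(12:50, 1); e <- n + sample(0:25, 1)
        nx <- sample(1:3, 1)
        net <- generatePathwayNetwork(nodeCount = n, edgeCount = e,
                                      receptorCount = sample(2:4, 1),
                                      exitCount = nx, seed = seed)
        expect_true(validObject(net))
        ed <- pathwayEdges(net)
        exits <- exitNodes(net)
        expect_length(exits, nx)
        # exits are sinks and detectExits finds them even without the
        # explicit declaration
        expect_false(any(ed$from %in% exits))
        auto <- net; auto@exitNodes <- character()
        expect_setequal(detectExits(auto), exits)
        # every node lies on some receptor -> exit path
        d <- shortestPathLengths(net)
        receptors <- grep("^R", pathwayNodes(net)$id, value = TRUE)
        for (v in pathwayNodes(net)$id) {
            fromReceptor <- v %in% receptors ||
                any(is.finite(d[receptors, v]))
            toExit <- v %in% exits || any(is.finite(d[v, exits]))
            expect_true(fromReceptor && toExit, label = paste(seed, v))
        }
    }
    expect_error(generatePathwayNetwork(nodeCount = 10, edgeCount = 5),
                 "at least")
    expect_error(generatePathwayNetwork(nodeCount = 5, receptorCount = 4,
                                        exitCount = 2, edgeCount = 8),
                 "smaller than")
})

test_that("score generator plants potencies on reference scale", {
    net <- generatePathwayNetwork(nodeCount = 20, edgeCount = 30,
                                  receptorCount = 3, seed = 2)
    planted <- list(full = list(targets = c("N1", "N2"), potency = 1),
                    none = list(targets = c("N1", "N2"), potency = 0))
    refs <- c(N1 = 5.0, N2 = 8.0)
    sm <- generateScores(net, 3, planted, referenceScores = refs, seed = 5)
    expect_identical(dim(dockingScores(sm)), c(3L, 2L))
    # noise-free potency 1 equals the reference score exactly
    expect_equal(dockingScores(sm)["full", ], refs)
    expect_equal(unname(dockingScores(sm)["none", ]), c(0, 0))
    # chained floor rule: zero potency everywhere -> zero NE decrease
    rpt <- screenCompounds(net, sm)
    tab <- screeningMetrics(rpt)
    expect_equal(tab$ne_decrease[tab$compound == "none"], 0)
    expect_equal(tab$ne_decrease[tab$compound == "compound01"], 0)
    # determinism
    sm2 <- generateScores(net, 3, planted, referenceScores = refs, seed = 5)
    expect_identical(dockingScores(sm), dockingScores(sm2))
    expect_error(generateScores(net, 1, list(x = list(targets = "ZZ",
                                                      potency = 1))),
                 "not in network")
})

test_that("a choke-point target beats an equal-potency peripheral one", {
    # T sits on every receptor -> exit path; P hangs off to the side
    edges <- data.frame(
        from = c("R1", "R2", "T", "X", "R1", "P"),
        to = c("T", "T", "X", "EXIT", "P", "X"))
    net <- PathwayNetwork(edges, exitNodes = "EXIT")
    refs <- c(T = 5, P = 5)
    sm <- generateScores(net, 2,
                         list(choke = list(targets = "T", potency = 1),
                              side = list(targets = "P", potency = 1)),
                         referenceScores = refs, seed = 1)
    tab <- screeningMetrics(screenCompounds(net, sm))
    expect_gt(tab$nf_decrease[tab$compound == "choke"],
              tab$nf_decrease[tab$compound == "side"])
    expect_equal(tab$compound[1], "choke")
})

test_that("NF ranking recovers planted potency order without noise", {
    taus <- vapply(1:20, function(seed) {
        net <- generatePathwayNetwork(nodeCount = 25, edgeCount = 40,
                                      receptorCount = 3, seed = seed)
        targets <- c("N2", "N5", "N8")
        potencies <- seq(0.55, 0.95, length.out = 6)
        planted <- setNames(lapply(potencies, function(p)
            list(targets = targets, potency = p)),
            paste0("cmpd", seq_along(potencies)))
        sm <- generateScores(net, length(planted), planted, seed = seed)
        tab <- screeningMetrics(
            screenCompounds(net, sm, rankingKey = "nf_decrease"))
        idx <- match(names(planted), tab$compound)
        cor(potencies, -idx, method = "kendall")
    }, numeric(1))
    expect_gte(mean(taus), 0.8)
    expect_gte(min(taus), 0.8)
})

test_that("bundled fixtures carry the published values", {
    t1 <- loadFixture("targets_table1")
    expect_equal(nrow(t1), 19L)
    expect_equal(t1$score[t1$target == "Thrombin"], 5.02)
    expect_equal(t1$score[t1$target == "Adenylate cyclase"], 6.38)
    expect_true(all(t1$score > 0))
    t2 <- loadFixture("compounds_table2")
    expect_equal(nrow(t2), 21L)
    expect_equal(sum(t2$glycoside), 7L)
    expect_equal(sum(t2$is_drug), 2L)
    sil <- t2[t2$compound == "Silybin", ]
    expect_equal(sil$inhibition, 0.73)
    expect_equal(sil$ne_decrease, 56.6)
    expect_equal(sil$nf_decrease, 96.6)
    # recomputed combination column follows the geometric-mean formula
    expect_equal(t2$combination_recomputed,
                 sqrt(t2$ne_decrease * t2$nf_decrease))
    net <- loadFixture("platelet_network")
    expect_s4_class(net, "PathwayNetwork")
    expect_equal(nrow(pathwayNodes(net)), 64L)
    expect_equal(nrow(pathwayEdges(net)), 91L)
    expect_equal(detectExits(net), "Platelet aggregation")
    # every reference-score target is a node of the curated network
    expect_true(all(t1$target %in% pathwayNodes(net)$id))
    expect_error(loadFixture("bogus"))
})
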