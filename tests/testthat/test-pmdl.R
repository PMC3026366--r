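test_that("the KT estimator unrolls to the closed-form code length", {
    # -log2(1/2 * 1/4 * 1/2 * 3/8) = 7 - log2(3)
    expect_equal(ktCodeLength(c(0, 1, 0, 1)), 7 - log2(3), tolerance = 1e-12)
    expect_equal(ktCodeLength(c(0, 0, 0, 0)),
                 -log2(0.5 * 0.75 * (2.5 / 3) * (3.5 / 4)), tolerance = 1e-12)
    # contexts keep independent counts
    x <- c(0L, 1L, 1L, 0L, 1L, 0L)
    ctx <- c(1L, 2L, 1L, 2L, 1L, 2L)
    expect_equal(ktCodeLength(x, ctx),
                 ktCodeLength(x[c(1, 3, 5)]) + ktCodeLength(x[c(2, 4, 6)]),
                 tolerance = 1e-12)
})

test_that("predictive code lengths match the sequential oracle", {
    vals <- rbind(G1 = c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 1L, 0L),
                  G2 = c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 1L),
                  G3 = c(0L, 0L, 1L, 1L, 1L, 0L, 1L, 0L, 0L, 1L))
    bm <- BinaryExpressionSeries(vals)
    tauMat <- matrix(1L, 3, 3); diag(tauMat) <- NA_integer_
    for (net in list(GeneNetwork(rownames(vals)),
                     GeneNetwork(rownames(vals),
                                 rbind(c("G2", "G1"), c("G1", "G3"), c("G2", "G3"))))) {
        want <- oDescriptionLength(net, vals, tauMat, predictive = TRUE)
        expect_equal(predictiveDataLength(net, bm), want[["data"]],
                     tolerance = 1e-9)
    }
})

test_that("a predictive parent shortens the code; a random one does not on average", {
    set.seed(41)
    x <- sample(0:1, 40, replace = TRUE)
    y <- c(0L, x[-40])
    bm <- BinaryExpressionSeries(rbind(A = x, B = y))
    none <- predictiveDataLength(GeneNetwork(c("A", "B")), bm)
    withEdge <- predictiveDataLength(GeneNetwork(c("A", "B"),
                                                 rbind(c("A", "B"))), bm)
    expect_lt(withEdge, none)

    deltas <- vapply(1:50, function(s) {
        set.seed(s)
        tgt <- sample(0:1, 30, replace = TRUE)
        noiseSrc <- sample(0:1, 30, replace = TRUE)
        bm2 <- BinaryExpressionSeries(rbind(R = noiseSrc, T = tgt))
        predictiveDataLength(GeneNetwork(c("R", "T"), rbind(c("R", "T"))), bm2) -
            predictiveDataLength(GeneNetwork(c("R", "T")), bm2)
    }, numeric(1))
    expect_gt(mean(deltas), 0)
})

test_that("CMI pruning removes the shortcut edge of a Markov chain", {
    bm <- chainSeries(40, seed = 6)
    net <- GeneNetwork(c("A", "C", "B"),
                       rbind(c("A", "C"), c("C", "B"), c("A", "B")))
    pruned <- cmiPrune(net, bm, cmiThreshold = 0.1)
    keys <- paste(networkEdges(pruned)$from, networkEdges(pruned)$to)
    expect_false("A B" %in% keys)
    expect_true(all(c("A C", "C B") %in% keys))
    # conditioning on all third genes reaches the same conclusion here
    prunedAll <- cmiPrune(net, bm, cmiThreshold = 0.1, conditionAll = TRUE)
    expect_false("A B" %in% paste(networkEdges(prunedAll)$from,
                                  networkEdges(prunedAll)$to))
})

test_that("pruning is vacuous without co-parents or at threshold zero", {
    bm <- chainSeries(40, seed = 12)
    single <- GeneNetwork(c("A", "C", "B"), rbind(c("A", "C"), c("C", "B")))
    expect_equal(networkEdges(cmiPrune(single, bm, cmiThreshold = 0.1)),
                 networkEdges(single))
    dense <- GeneNetwork(c("A", "C", "B"),
                         rbind(c("A", "B"), c("C", "B"), c("A", "C")))
    expect_equal(networkEdges(cmiPrune(dense, bm, cmiThreshold = 0)),
                 networkEdges(dense))
})

test_that("pruning only ever removes edges", {
    for (s in 1:10) {
        bm <- randomBinarySeries(4, 20, seed = 500 + s)
        sc <- scoreMatrix(bm)
        net <- candidateNetwork(sc, stats::median(sc, na.rm = TRUE))
        pruned <- cmiPrune(net, bm, cmiThreshold = 0.1)
        before <- paste(networkEdges(net)$from, networkEdges(net)$to)
        after <- paste(networkEdges(pruned)$from, networkEdges(pruned)$to)
        expect_true(all(after %in% before))
    }
})

test_that("the PMDL sweep attains the brute-force predictive optimum", {
    for (s in 1:10) {
        n <- sample(3:4, 1)
        m <- sample(8:12, 1)
        bm <- randomBinarySeries(n, m, seed = 200 + s)
        fit <- inferPMDL(bm, cmiThreshold = 0)
        best <- min(sweepTrace(fit)$totalBits)
        tauMat <- matrix(1L, n, n); diag(tauMat) <- NA_integer_
        expect_equal(best,
                     oSweepBestTotal(exprValues(bm), tauMat, 0,
                                     predictive = TRUE), tolerance = 1e-9)
    }
})

test_that("threshold selection and pruning compose as documented", {
    bm <- chainSeries(40, seed = 30)
    # zero CMI threshold: pipeline equals the sweep-only selection
    fit0 <- inferPMDL(bm, cmiThreshold = 0)
    expect_equal(networkEdges(inferredNetwork(fit0)),
                 networkEdges(fit0@prePruneNetwork))
    # published threshold: pruned edge set is a subset of the selection
    fit <- inferPMDL(bm, cmiThreshold = 0.1)
    before <- paste(networkEdges(fit@prePruneNetwork)$from,
                    networkEdges(fit@prePruneNetwork)$to)
    after <- paste(networkEdges(inferredNetwork(fit))$from,
                   networkEdges(inferredNetwork(fit))$to)
    expect_true(all(after %in% before))
})
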