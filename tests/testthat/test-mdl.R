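test_that("score matrices hold pairwise TLMI at each pair's lag", {
    set.seed(17)
    x <- sample(0:1, 30, replace = TRUE)
    y <- c(0L, x[-30])                      # y copies x with unit delay
    bm <- BinaryExpressionSeries(rbind(A = x, B = y))
    sc <- scoreMatrix(bm)                   # unit-lag mode
    expect_equal(sc["A", "B"], binaryEntropy(x[1:29]), tolerance = 1e-12)
    expect_true(is.na(sc["A", "A"]))

    # independent uniform rows score near zero
    bm2 <- randomBinarySeries(4, 60, seed = 4)
    sc2 <- scoreMatrix(bm2)
    expect_lt(max(sc2, na.rm = TRUE), 0.15)

    # lagged mode uses the per-pair lags of the worked example
    p <- lagExamplePair()
    bmL <- BinaryExpressionSeries(rbind(A = p$a, B = p$b))
    lm <- computeLagMatrix(bmL)
    scL <- scoreMatrix(bmL, lm)
    expect_equal(scL["A", "B"], tlmi(p$a, p$b, 1), tolerance = 1e-12)
    expect_equal(scL["B", "A"], tlmi(p$b, p$a, 3), tolerance = 1e-12)
})

test_that("threshold candidates range from the complete to the empty model", {
    bm <- randomBinarySeries(3, 12, seed = 2)
    sc <- scoreMatrix(bm)
    full <- candidateNetwork(sc, min(sc, na.rm = TRUE))
    expect_equal(nEdges(full), 6L)          # complete digraph minus loops
    top <- candidateNetwork(sc, max(sc, na.rm = TRUE))
    expect_gte(nEdges(top), 1L)
    expect_true(all(networkEdges(top)$from != networkEdges(top)$to))
    expect_equal(nEdges(candidateNetwork(sc, Inf)), 0L)
})

test_that("candidate networks are nested and model length grows as the threshold drops", {
    bm <- randomBinarySeries(4, 15, seed = 8)
    sc <- scoreMatrix(bm)
    thetas <- sort(unique(sc[!is.na(sc)]), decreasing = TRUE)
    prevEdges <- character(0)
    prevModel <- -Inf
    for (th in thetas) {
        net <- candidateNetwork(sc, th)
        e <- networkEdges(net)
        keys <- paste(e$from, e$to)
        expect_true(all(prevEdges %in% keys))
        dl <- descriptionLength(net, bm)
        expect_gte(dl[["model"]], prevModel)
        prevEdges <- keys
        prevModel <- dl[["model"]]
    }
})

test_that("description lengths match an independent brute-force coder", {
    # a printed 3-gene toy
    vals <- rbind(G1 = c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L),
                  G2 = c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 0L),
                  G3 = c(0L, 0L, 1L, 1L, 1L, 0L, 1L, 0L))
    bm <- BinaryExpressionSeries(vals)
    tauMat <- matrix(1L, 3, 3); diag(tauMat) <- NA_integer_
    nets <- list(GeneNetwork(rownames(vals)),
                 GeneNetwork(rownames(vals), rbind(c("G1", "G2"))),
                 GeneNetwork(rownames(vals),
                             rbind(c("G1", "G3"), c("G2", "G3"), c("G3", "G1"))))
    for (net in nets) {
        got <- descriptionLength(net, bm)
        want <- oDescriptionLength(net, vals, tauMat)
        expect_equal(got[["model"]], want[["model"]])
        expect_equal(got[["data"]], want[["data"]], tolerance = 1e-9)
    }
})

test_that("a perfectly predictive parent shrinks the data code to smoothing slack", {
    set.seed(23)
    x <- sample(0:1, 40, replace = TRUE)
    y <- c(0L, x[-40])
    bm <- BinaryExpressionSeries(rbind(A = x, B = y))
    empty <- descriptionLength(GeneNetwork(c("A", "B")), bm)
    withEdge <- descriptionLength(GeneNetwork(c("A", "B"),
                                              rbind(c("A", "B"))), bm)
    expect_lt(withEdge[["data"]], empty[["data"]])
    # B's contribution alone is near zero: bound it by the two-context slack
    bBits <- withEdge[["data"]] -
        oGeneCode(x, matrix(integer(0), 0, 40), integer(0))
    expect_lt(bBits, 3)
})

test_that("the MDL sweep attains the brute-force optimum and breaks ties sparsely", {
    for (s in 1:10) {
        n <- sample(3:4, 1)
        m <- sample(8:12, 1)
        bm <- randomBinarySeries(n, m, seed = 100 + s)
        fit <- inferMDL(bm, lambda = 0.2)
        tr <- sweepTrace(fit)
        best <- min(tr$totalBits)
        tauMat <- matrix(1L, n, n); diag(tauMat) <- NA_integer_
        expect_equal(best, oSweepBestTotal(exprValues(bm), tauMat, 0.2),
                     tolerance = 1e-9)
        # tie-break: no sparser candidate achieves the same total
        atBest <- tr[abs(tr$totalBits - best) <= 1e-9, ]
        expect_equal(chosenThreshold(fit), max(atBest$threshold))
    }
})

test_that("a perfect unit-lag dependency is recovered by MDL", {
    set.seed(31)
    x <- sample(0:1, 24, replace = TRUE)
    bm <- BinaryExpressionSeries(rbind(A = x, B = c(0L, x[-24])))
    fit <- inferMDL(bm, lambda = 0.2)
    e <- networkEdges(inferredNetwork(fit))
    expect_true(any(e$from == "A" & e$to == "B"))
})

test_that("parent caps are enforced by name", {
    bm <- randomBinarySeries(3, 10, seed = 77)
    net <- GeneNetwork(geneIds(bm), rbind(c("G1", "G3"), c("G2", "G3")))
    expect_error(descriptionLength(net, bm, maxParents = 1), "G3")
})
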