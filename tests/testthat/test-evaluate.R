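test_that("confusion counts respect edge direction", {
    t3 <- GeneNetwork(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
    expect_equal(confusionCounts(t3, t3), c(Ce = 2L, Me = 0L, Fe = 0L))
    disj <- GeneNetwork(c("A", "B", "C"), rbind(c("C", "A")))
    expect_equal(confusionCounts(t3, disj), c(Ce = 0L, Me = 2L, Fe = 1L))
    flip <- GeneNetwork(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B")))
    expect_equal(confusionCounts(t3, flip), c(Ce = 1L, Me = 1L, Fe = 1L))
    # undirected matching forgives the reversed edge
    expect_equal(confusionCounts(t3, flip, undirected = TRUE),
                 c(Ce = 2L, Me = 0L, Fe = 0L))
    other <- GeneNetwork(c("A", "B", "Z"), rbind(c("A", "B")))
    expect_error(confusionCounts(t3, other), "different gene universes")
})

test_that("precision and recall follow their defining ratios", {
    expect_equal(precisionRecall(3, Me = 0, Fe = 9)$precision, 0.25)
    expect_equal(precisionRecall(1, Me = 0, Fe = 6)$precision, 1 / 7,
                 tolerance = 1e-12)
    r <- precisionRecall(c(Ce = 4, Me = 2, Fe = 1))
    expect_equal(r$recall, 4 / 6)
    expect_equal(r$ratio, r$recall / r$precision)
    # degenerate conventions keep sweeps total
    z <- precisionRecall(c(Ce = 0, Me = 0, Fe = 0))
    expect_equal(c(z$precision, z$recall, z$ratio), c(1, 1, 1))
    expect_equal(precisionRecall(c(Ce = 0, Me = 3, Fe = 0))$precision, 1)
    expect_error(precisionRecall(c(Ce = -1, Me = 0, Fe = 0)), "non-negative")
})

test_that("swapping the two networks' roles exchanges Me and Fe", {
    set.seed(61)
    for (rep in 1:10) {
        g <- sprintf("G%d", 1:5)
        mk <- function() {
            pairs <- expand.grid(from = g, to = g, stringsAsFactors = FALSE)
            pairs <- pairs[pairs$from != pairs$to, ]
            pick <- pairs[sample(nrow(pairs), sample(2:8, 1)), ]
            GeneNetwork(g, as.matrix(pick))
        }
        a <- mk(); b <- mk()
        ab <- confusionCounts(a, b); ba <- confusionCounts(b, a)
        expect_equal(ab[["Ce"]], ba[["Ce"]])
        expect_equal(ab[["Me"]], ba[["Fe"]])
        expect_equal(ab[["Fe"]], ba[["Me"]])
    }
})

test_that("saturation sweeps emit one row per prefix with no state leakage", {
    ds <- saturationDataset(5, 75, seed = 71)
    sw <- saturationSweep(ds$series, ds$network, method = "pmdl",
                          timeLagged = TRUE)
    expect_equal(nrow(sw), 13L)
    expect_equal(sw$mUsed, seq(15L, 75L, by = 5L))
    expect_true(all(sw$precision >= 0 & sw$precision <= 1))

    # each row equals a standalone run on the truncated series
    sub <- BinaryExpressionSeries(exprValues(ds$series)[, 1:20])
    fit <- inferPMDL(sub, timeLagged = TRUE)
    direct <- precisionRecall(confusionCounts(ds$network, inferredNetwork(fit)))
    expect_equal(sw$precision[sw$mUsed == 20], direct$precision)
    expect_equal(sw$recall[sw$mUsed == 20], direct$recall)

    # 15-point input yields a single row; shorter input errors
    one <- saturationSweep(BinaryExpressionSeries(exprValues(ds$series)[, 1:15]),
                           ds$network)
    expect_equal(nrow(one), 1L)
    expect_error(saturationSweep(BinaryExpressionSeries(exprValues(ds$series)[, 1:10]),
                                 ds$network), "time points")
})

test_that("the MI curve study averages the documented quantities", {
    v <- rbind(G1 = c(0L, 1L, 1L, 0L, 1L, 0L),
               G2 = c(1L, 1L, 0L, 0L, 1L, 1L),
               G3 = c(0L, 0L, 1L, 1L, 0L, 1L))
    bm <- BinaryExpressionSeries(v)
    cur <- miCurveStudy(bm, 6)
    expect_equal(cur$meanEntropy, mean(apply(v, 1, binaryEntropy)))
    ces <- mis <- c()
    for (i in 1:3) for (j in 1:3) if (i != j) {
        ces <- c(ces, jointEntropy(v[i, ], v[j, ]) - binaryEntropy(v[j, ]))
        mis <- c(mis, mutualInformation(v[i, ], v[j, ]))
    }
    expect_equal(cur$meanCondEntropy, mean(ces), tolerance = 1e-12)
    expect_equal(cur$meanMI, mean(mis), tolerance = 1e-12)

    # constant data carries no information at any prefix
    flat <- BinaryExpressionSeries(rbind(G1 = rep(0L, 8), G2 = rep(0L, 8)))
    curFlat <- miCurveStudy(flat, c(4, 8))
    expect_true(all(unlist(curFlat[, -1]) == 0))
    expect_error(miCurveStudy(bm, 7), "prefix")
})

test_that("averaged over seeds, entropy grows and MI decays with data size", {
    h15 <- h100 <- mi15 <- mi100 <- numeric(0)
    for (s in 1:12) {
        model <- randomBooleanNetwork(5, noise = 0.05, seed = 900 + s)
        bm <- simulateSeries(model, 100)
        cur <- miCurveStudy(bm, c(15, 100))
        h15 <- c(h15, cur$meanEntropy[1]);  h100 <- c(h100, cur$meanEntropy[2])
        mi15 <- c(mi15, cur$meanMI[1]);     mi100 <- c(mi100, cur$meanMI[2])
    }
    expect_gt(mean(h100), mean(h15))
    expect_lt(mean(mi100), mean(mi15))
})
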