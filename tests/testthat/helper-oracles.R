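# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use a different code path (string keys + table())
# than the package internals (integer tabulation).

`%||%` <- function(a, b) if (is.null(a)) b else a

oEntropy <- function(x) {
    p <- as.numeric(table(x)) / length(x)
    -sum(p * log2(p))
}

oJointEntropy <- function(...) {
    key <- do.call(paste, c(list(...), sep = "|"))
    p <- as.numeric(table(key)) / length(key)
    -sum(p * log2(p))
}

oMI <- function(a, b) oEntropy(a) + oEntropy(b) - oJointEntropy(a, b)

oCMI <- function(a, b, c)
    oJointEntropy(a, c) + oJointEntropy(b, c) - oEntropy(c) -
        oJointEntropy(a, b, c)

# code length of one gene given parents, contexts keyed by strings
oGeneCode <- function(target, parentRows, taus, noParentTau = 1,
                      predictive = FALSE) {
    m <- length(target)
    s <- if (length(taus)) max(taus) + 1 else noParentTau + 1
    idx <- s:m
    keys <- vapply(idx, function(t) {
        if (!length(taus)) return("ctx")
        paste(vapply(seq_along(taus),
                     function(p) parentRows[p, t - taus[p]], integer(1)),
              collapse = "|")
    }, character(1))
    y <- target[idx]
    bits <- 0
    if (predictive) {
        cnt <- list()
        for (i in seq_along(y)) {
            cc <- cnt[[keys[i]]] %||% c(0, 0)
            bits <- bits - log2((cc[y[i] + 1] + 0.5) / (sum(cc) + 1))
            cc[y[i] + 1] <- cc[y[i] + 1] + 1
            cnt[[keys[i]]] <- cc
        }
    } else {
        for (i in seq_along(y)) {
            same <- keys == keys[i]
            bits <- bits - log2((sum(same & y == y[i]) + 0.5) /
                                (sum(same) + 1))
        }
    }
    bits
}

# full description length of a network by brute force
oDescriptionLength <- function(net, vals, tauMat, cptEntryBits = 8,
                               predictive = FALSE) {
    ids <- rownames(vals)
    n <- length(ids)
    e <- networkEdges(net)
    modelBits <- 0
    dataBits <- 0
    for (j in seq_len(n)) {
        pj <- match(e$from[e$to == ids[j]], ids)
        k <- length(pj)
        modelBits <- modelBits + k * log2(n) + 2^k * cptEntryBits
        taus <- if (k) vapply(pj, function(i) tauMat[i, j], integer(1))
                else integer(0)
        dataBits <- dataBits + oGeneCode(vals[j, ], vals[pj, , drop = FALSE],
                                         taus, predictive = predictive)
    }
    c(model = modelBits, data = dataBits)
}

# brute-force threshold sweep: best achievable total over all distinct
# thresholds (scores recomputed from manually trimmed sequences)
oSweepBestTotal <- function(vals, tauMat, lambda, predictive = FALSE,
                            cptEntryBits = 8) {
    ids <- rownames(vals)
    n <- length(ids)
    m <- ncol(vals)
    sc <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (i == j) next
            tau <- tauMat[i, j]
            sc[i, j] <- max(oMI(vals[i, 1:(m - tau)], vals[j, (tau + 1):m]), 0)
        }
    }
    best <- Inf
    for (th in c(unique(sc[!is.na(sc)]), Inf)) {
        hit <- which(!is.na(sc) & sc >= th, arr.ind = TRUE)
        net <- GeneNetwork(ids, cbind(ids[hit[, 1]], ids[hit[, 2]]))
        dl <- oDescriptionLength(net, vals, tauMat, cptEntryBits,
                                 predictive = predictive)
        tot <- if (predictive) dl[["data"]]
               else lambda * dl[["model"]] + dl[["data"]]
        best <- min(best, tot)
    }
    best
}

# random 0/1 matrix wrapped as a BinaryExpressionSeries
randomBinarySeries <- function(n, m, seed) {
    set.seed(seed)
    BinaryExpressionSeries(matrix(sample(0:1, n * m, replace = TRUE), n, m,
                                  dimnames = list(sprintf("G%d", 1:n), NULL)))
}

# noiseless Markov-chain data A -> C -> B (unit delays), A exogenous
chainSeries <- function(m, seed) {
    set.seed(seed)
    A <- sample(0:1, m, replace = TRUE)
    C <- c(sample(0:1, 1), A[-m])
    B <- c(sample(0:1, 1), C[-m])
    BinaryExpressionSeries(rbind(A = A, C = C, B = B))
}

# the worked two-gene lag configuration: regulator up at t = 2 with its
# next change at t = 6; target up at t = 3 with no further change
lagExamplePair <- function() {
    list(a = c(0L, 1L, 1L, 1L, 1L, 0L, 0L),
         b = c(0L, 0L, 1L, 1L, 1L, 1L, 1L))
}
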