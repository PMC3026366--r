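# Network-MDL inference: every observed TLMI value is tried as an edge
# threshold; the candidate network minimizing lambda * model length +
# data length (both in bits) is selected.

.CPT_GUARD <- 2^16

.tauOf <- function(lags, i, j) lags@tau[i, j]

# Code length, in bits, of one gene's time course given its parents.
# Contexts are the parents' states at t - tau_p; the coded window is the
# common overlap [max(tau) + 1, m] (noParentTau + 1 .. m with no parents).
# static: Laplace(+1/2)-smoothed conditional frequencies over the window.
# predictive: Krichevsky-Trofimov sequential (count + 1/2)/(total + 1).
.geneCodeLength <- function(target, parentRows, taus, noParentTau = 1L,
                            predictive = FALSE) {
    m <- length(target)
    k <- length(taus)
    s <- if (k == 0L) noParentTau + 1L else max(taus) + 1L
    idx <- s:m
    y <- target[idx]
    ctx <- rep(1L, length(idx))
    if (k > 0L)
        for (p in seq_len(k))
            ctx <- ctx + parentRows[p, idx - taus[p]] * 2L^(p - 1L)
    nctx <- 2L^k
    if (predictive) {
        cnt <- matrix(0, nctx, 2L)
        bits <- 0
        for (t in seq_along(y)) {
            i <- ctx[t]
            pr <- (cnt[i, y[t] + 1L] + 0.5) / (sum(cnt[i, ]) + 1)
            bits <- bits - log2(pr)
            cnt[i, y[t] + 1L] <- cnt[i, y[t] + 1L] + 1
        }
        bits
    } else {
        cnt <- matrix(0, nctx, 2L)
        for (t in seq_along(y))
            cnt[ctx[t], y[t] + 1L] <- cnt[ctx[t], y[t] + 1L] + 1
        tot <- rowSums(cnt)
        -sum(log2((cnt[cbind(ctx, y + 1L)] + 0.5) / (tot[ctx] + 1)))
    }
}

.parentIndexList <- function(net, ids) {
    e <- net@edges
    lapply(ids, function(g) match(e[e[, 2L] == g, 1L], ids))
}

#' Pairwise (time-lagged) mutual-information score matrix
#'
#' Entry (i, j) is TLMI(gene_i -> gene_j) at the pair's lag tau(i -> j)
#' from the supplied lag matrix, or at the conventional unit lag when
#' \code{lags} is \code{NULL}.  Because every ordered pair carries its own
#' lag, the matrix is not symmetric even in unit-lag mode.
#'
#' @param bm a \code{\link{BinaryExpressionSeries}}.
#' @param lags a \code{\link{LagMatrix}}, or \code{NULL} for unit lags.
#' @param minOverlap minimum lag-trimmed length (default 4).
#' @return numeric n x n matrix of scores in bits, diagonal \code{NA}.
#' @export
scoreMatrix <- function(bm, lags = NULL, minOverlap = 4L) {
    stopifnot(is(bm, "BinaryExpressionSeries"))
    v <- bm@values
    ids <- rownames(v)
    n <- nrow(v)
    if (is.null(lags))
        lags <- unitLagMatrix(ids)
    sc <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n))
        for (j in seq_len(n))
            if (i != j)
                sc[i, j] <- tlmi(v[i, ], v[j, ], .tauOf(lags, i, j),
                                 minOverlap = minOverlap)
    sc
}

#' Candidate network induced by a score threshold
#'
#' The network containing the directed edge i -> j exactly when
#' score(i, j) >= theta.  Sweeping theta over every observed score
#' realizes every distinct candidate; theta = +Inf gives the empty model.
#'
#' @param scores score matrix from \code{\link{scoreMatrix}}.
#' @param theta threshold in bits.
#' @return a \code{\link{GeneNetwork}}.
#' @export
candidateNetwork <- function(scores, theta) {
    ids <- rownames(scores)
    hit <- which(!is.na(scores) & scores >= theta, arr.ind = TRUE)
    GeneNetwork(genes = ids,
                edges = cbind(ids[hit[, 1L]], ids[hit[, 2L]]))
}

#' Description length of a candidate network
#'
#' Two-part code.  Model length charges each gene k_j * log2(n) bits to
#' name its k_j parents plus \code{cptEntryBits} bits per entry of its
#' 2^k_j conditional-probability table.  Data length is the
#' Laplace(+1/2)-smoothed conditional code of every gene's time course
#' given its parents' lag-shifted states, summed over genes; each parent
#' contributes its own pairwise lag and the gene is coded over the common
#' overlap window.  The reported components are unweighted; the MDL sweep
#' combines them as lambda * model + data.
#'
#' @param net candidate \code{\link{GeneNetwork}} over \code{bm}'s genes.
#' @param bm a \code{\link{BinaryExpressionSeries}}.
#' @param lags a \code{\link{LagMatrix}} or \code{NULL} for unit lags.
#' @param cptEntryBits bits charged per CPT entry (default 8).
#' @param maxParents optional per-gene parent cap; exceeding it is an
#'   error naming the gene.
#' @param defaultTau lag used to trim parentless genes' windows.
#' @return named numeric vector \code{c(model = , data = )}, in bits.
#' @export
descriptionLength <- function(net, bm, lags = NULL, cptEntryBits = 8,
                              maxParents = NULL, defaultTau = 1L) {
    stopifnot(is(net, "GeneNetwork"), is(bm, "BinaryExpressionSeries"))
    v <- bm@values
    ids <- rownames(v)
    if (!setequal(net@genes, ids))
        stop("network and expression series cover different genes",
             call. = FALSE)
    if (is.null(lags))
        lags <- unitLagMatrix(ids)
    n <- length(ids)
    parents <- .parentIndexList(net, ids)
    modelBits <- 0
    dataBits <- 0
    for (j in seq_len(n)) {
        pj <- parents[[j]]
        k <- length(pj)
        if (!is.null(maxParents) && k > maxParents)
            stop(sprintf("gene '%s' has %d parents (cap %d)",
                         ids[j], k, maxParents), call. = FALSE)
        if (2^k > .CPT_GUARD)
            warning(sprintf("gene '%s': CPT with 2^%d entries may exhaust memory",
                            ids[j], k), call. = FALSE)
        modelBits <- modelBits + k * log2(n) + 2^k * cptEntryBits
        taus <- if (k) vapply(pj, function(i) .tauOf(lags, i, j), integer(1L))
                else integer(0)
        dataBits <- dataBits + .geneCodeLength(v[j, ],
                                               v[pj, , drop = FALSE], taus,
                                               noParentTau = as.integer(defaultTau))
    }
    c(model = modelBits, data = dataBits)
}

.thresholdSweep <- function(bm, lags, lambda, cptEntryBits, maxParents,
                            defaultTau, minOverlap, predictive) {
    scores <- scoreMatrix(bm, lags, minOverlap = minOverlap)
    thetas <- c(sort(unique(scores[!is.na(scores)])), Inf)
    trace <- data.frame(threshold = thetas, modelBits = NA_real_,
                        dataBits = NA_real_, totalBits = NA_real_,
                        nEdges = NA_integer_)
    nets <- vector("list", length(thetas))
    for (q in seq_along(thetas)) {
        net <- candidateNetwork(scores, thetas[q])
        nets[[q]] <- net
        if (!is.null(maxParents) &&
            any(tabulate(match(net@edges[, 2L], rownames(bm@values)),
                         nbins = nrow(bm@values)) > maxParents)) {
            trace$totalBits[q] <- Inf
            trace$nEdges[q] <- nrow(net@edges)
            next
        }
        if (predictive) {
            db <- predictiveDataLength(net, bm, lags, defaultTau = defaultTau)
            trace$modelBits[q] <- 0
            trace$dataBits[q] <- db
            trace$totalBits[q] <- db
        } else {
            dl <- descriptionLength(net, bm, lags, cptEntryBits = cptEntryBits,
                                    maxParents = maxParents,
                                    defaultTau = defaultTau)
            trace$modelBits[q] <- dl[["model"]]
            trace$dataBits[q] <- dl[["data"]]
            trace$totalBits[q] <- lambda * dl[["model"]] + dl[["data"]]
        }
        trace$nEdges[q] <- nrow(net@edges)
    }
    best <- max(which(trace$totalBits <= min(trace$totalBits) + 1e-9))
    list(net = nets[[best]], threshold = thetas[best], trace = trace)
}

#' Infer a network by the network-MDL principle
#'
#' Computes the (time-lagged) mutual-information score matrix, tries every
#' distinct score value -- plus a +Inf sentinel for the empty model -- as
#' an edge threshold, evaluates each induced candidate's description
#' length, and returns the candidate minimizing
#' lambda * model length + data length.  Ties are broken toward the larger
#' threshold, i.e. the sparser network.
#'
#' @param bm a \code{\link{BinaryExpressionSeries}}.
#' @param lambda weight on the model length (the published fine-tuning
#'   knob: 0.2 for synthetic runs, 0.1 for biological runs).
#' @param timeLagged if \code{TRUE}, use event-based pairwise lags from
#'   \code{\link{computeLagMatrix}}; otherwise the unit-delay legacy mode.
#' @param defaultTau,minOverlap lag-handling parameters, shared with
#'   \code{\link{computeLagMatrix}}.
#' @param cptEntryBits,maxParents model-length parameters, see
#'   \code{\link{descriptionLength}}.
#' @return a \code{\link{GRNInference}}.
#' @examples
#' model <- randomBooleanNetwork(5, seed = 7)
#' bm <- simulateSeries(model, 40, seed = 8)
#' inferMDL(bm, timeLagged = TRUE)
#' @export
inferMDL <- function(bm, lambda = 0.2, timeLagged = FALSE, defaultTau = 1L,
                     minOverlap = 4L, cptEntryBits = 8, maxParents = NULL) {
    stopifnot(is(bm, "BinaryExpressionSeries"), lambda >= 0)
    lags <- if (timeLagged)
        computeLagMatrix(bm, defaultTau = defaultTau, minOverlap = minOverlap)
    else unitLagMatrix(rownames(bm@values))
    sw <- .thresholdSweep(bm, lags, lambda, cptEntryBits, maxParents,
                          defaultTau, minOverlap, predictive = FALSE)
    new("GRNInference", network = sw$net, prePruneNetwork = sw$net,
        threshold = sw$threshold, trace = sw$trace, lags = lags,
        method = "mdl")
}
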