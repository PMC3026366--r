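# Predictive-MDL inference: the threshold sweep scores candidates by a
# sequential predictive code length alone (no model-length term), after
# which conditional mutual information prunes indirect edges.

#' Predictive (sequential) code length of a network
#'
#' Codes every gene's time course with the Krichevsky-Trofimov sequential
#' estimator, one Bernoulli context per joint parent state: at each coded
#' time point the probability assigned to the observed symbol is
#' (count so far + 1/2) / (total so far + 1) within its context, processed
#' in time order.  This is a true predictive code -- it never sees the
#' future and needs no separately coded model -- so candidate networks can
#' be compared on this quantity alone.
#'
#' @param net candidate \code{\link{GeneNetwork}} over \code{bm}'s genes.
#' @param bm a \code{\link{BinaryExpressionSeries}}.
#' @param lags a \code{\link{LagMatrix}} or \code{NULL} for unit lags.
#' @param maxParents optional per-gene parent cap.
#' @param defaultTau lag used to trim parentless genes' windows.
#' @return total code length in bits.
#' @seealso \code{\link{ktCodeLength}} for the raw estimator.
#' @export
predictiveDataLength <- function(net, bm, lags = NULL, maxParents = NULL,
                                 defaultTau = 1L) {
    stopifnot(is(net, "GeneNetwork"), is(bm, "BinaryExpressionSeries"))
    v <- bm@values
    ids <- rownames(v)
    if (!setequal(net@genes, ids))
        stop("network and expression series cover different genes",
             call. = FALSE)
    if (is.null(lags))
        lags <- unitLagMatrix(ids)
    parents <- .parentIndexList(net, ids)
    bits <- 0
    for (j in seq_along(ids)) {
        pj <- parents[[j]]
        if (!is.null(maxParents) && length(pj) > maxParents)
            stop(sprintf("gene '%s' has %d parents (cap %d)",
                         ids[j], length(pj), maxParents), call. = FALSE)
        taus <- if (length(pj))
            vapply(pj, function(i) .tauOf(lags, i, j), integer(1L))
        else integer(0)
        bits <- bits + .geneCodeLength(v[j, ], v[pj, , drop = FALSE], taus,
                                       noParentTau = as.integer(defaultTau),
                                       predictive = TRUE)
    }
    bits
}

#' Krichevsky-Trofimov code length of a binary sequence
#'
#' Sequential code length of \code{x} under the KT estimator, optionally
#' with a context label per symbol (each context keeps its own counts).
#' The t-th symbol is charged -log2((count + 1/2) / (total + 1)) using the
#' counts accumulated so far in its context.
#'
#' @param x 0/1 vector.
#' @param contexts optional vector of context labels, same length as
#'   \code{x}; \code{NULL} for a single context.
#' @return code length in bits.
#' @examples
#' ktCodeLength(c(0, 1, 0, 1))  # 5.415 bits
#' @export
ktCodeLength <- function(x, contexts = NULL) {
    x <- .checkBinarySeq(x)
    if (is.null(contexts))
        contexts <- rep(1L, length(x))
    stopifnot(length(contexts) == length(x))
    ctx <- as.integer(factor(contexts))
    cnt <- matrix(0, max(ctx), 2L)
    bits <- 0
    for (t in seq_along(x)) {
        i <- ctx[t]
        pr <- (cnt[i, x[t] + 1L] + 0.5) / (sum(cnt[i, ]) + 1)
        bits <- bits - log2(pr)
        cnt[i, x[t] + 1L] <- cnt[i, x[t] + 1L] + 1
    }
    bits
}

#' Prune indirect edges by conditional mutual information
#'
#' For every edge i -> j, the dependence of j on i is re-examined given
#' each other current regulator k of j (or every third gene when
#' \code{conditionAll = TRUE}): if TLCMI(i; j | k) at the pair's lag falls
#' below \code{cmiThreshold} for any such k, the edge is marked as
#' indirect.  All marked edges are removed simultaneously after the full
#' scan, so the result does not depend on scan order.
#'
#' @param net \code{\link{GeneNetwork}} from threshold selection.
#' @param bm a \code{\link{BinaryExpressionSeries}}.
#' @param lags a \code{\link{LagMatrix}} or \code{NULL} for unit lags.
#' @param cmiThreshold pruning threshold in bits (published value: 0.1).
#' @param conditionAll condition on every third gene instead of only j's
#'   current co-regulators (for sensitivity analysis).
#' @param minOverlap minimum lag-trimmed length (default 4).
#' @return the pruned \code{\link{GeneNetwork}}.
#' @export
cmiPrune <- function(net, bm, lags = NULL, cmiThreshold = 0.1,
                     conditionAll = FALSE, minOverlap = 4L) {
    stopifnot(is(net, "GeneNetwork"), is(bm, "BinaryExpressionSeries"),
              cmiThreshold >= 0)
    v <- bm@values
    ids <- rownames(v)
    if (is.null(lags))
        lags <- unitLagMatrix(ids)
    e <- net@edges
    if (nrow(e) == 0L)
        return(net)
    drop <- logical(nrow(e))
    for (r in seq_len(nrow(e))) {
        i <- match(e[r, 1L], ids)
        j <- match(e[r, 2L], ids)
        ks <- if (conditionAll) setdiff(seq_along(ids), c(i, j))
              else setdiff(match(e[e[, 2L] == ids[j], 1L], ids), c(i, j))
        for (k in ks) {
            if (tlcmi(v[i, ], v[j, ], v[k, ], .tauOf(lags, i, j),
                      minOverlap = minOverlap) < cmiThreshold) {
                drop[r] <- TRUE
                break
            }
        }
    }
    GeneNetwork(genes = net@genes, edges = e[!drop, , drop = FALSE])
}

#' Infer a network by the predictive-MDL principle
#'
#' Computes the (time-lagged) mutual-information score matrix, selects the
#' threshold whose induced network minimizes the sequential predictive
#' code length (ties toward the sparser network), and then removes
#' indirect edges whose time-lagged conditional mutual information given a
#' co-regulator falls below \code{cmiThreshold}.
#'
#' @param bm a \code{\link{BinaryExpressionSeries}}.
#' @param cmiThreshold CMI pruning threshold in bits (published: 0.1).
#' @param timeLagged if \code{TRUE}, use event-based pairwise lags;
#'   otherwise the unit-delay legacy mode.
#' @param conditionAll see \code{\link{cmiPrune}}.
#' @param defaultTau,minOverlap lag-handling parameters.
#' @param maxParents optional per-gene parent cap.
#' @return a \code{\link{GRNInference}}; \code{inferredNetwork} is the
#'   pruned network, slot \code{prePruneNetwork} the sweep's selection.
#' @examples
#' model <- randomBooleanNetwork(5, seed = 7)
#' bm <- simulateSeries(model, 40, seed = 8)
#' inferPMDL(bm, timeLagged = TRUE)
#' @export
inferPMDL <- function(bm, cmiThreshold = 0.1, timeLagged = FALSE,
                      conditionAll = FALSE, defaultTau = 1L,
                      minOverlap = 4L, maxParents = NULL) {
    stopifnot(is(bm, "BinaryExpressionSeries"))
    lags <- if (timeLagged)
        computeLagMatrix(bm, defaultTau = defaultTau, minOverlap = minOverlap)
    else unitLagMatrix(rownames(bm@values))
    sw <- .thresholdSweep(bm, lags, lambda = 0, cptEntryBits = 0,
                          maxParents = maxParents, defaultTau = defaultTau,
                          minOverlap = minOverlap, predictive = TRUE)
    pruned <- cmiPrune(sw$net, bm, lags, cmiThreshold = cmiThreshold,
                       conditionAll = conditionAll, minOverlap = minOverlap)
    new("GRNInference", network = pruned, prePruneNetwork = sw$net,
        threshold = sw$threshold, trace = sw$trace, lags = lags,
        method = "pmdl")
}
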