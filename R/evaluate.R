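# Precision/recall evaluation against a reference network, data-size
# sweeps, and the mutual-information saturation curve study.

#' Directed-edge confusion counts
#'
#' Compares two networks over the same gene universe by exact directed
#' edge matching (i -> j and j -> i are different edges).
#'
#' @param trueNet reference \code{\link{GeneNetwork}}.
#' @param inferred inferred \code{\link{GeneNetwork}}.
#' @param undirected if \code{TRUE}, match edges regardless of direction.
#' @return named integer vector \code{c(Ce = , Me = , Fe = )}: edges in
#'   both networks, edges only in the reference, edges only in the
#'   inferred network.
#' @export
confusionCounts <- function(trueNet, inferred, undirected = FALSE) {
    stopifnot(is(trueNet, "GeneNetwork"), is(inferred, "GeneNetwork"))
    if (!setequal(trueNet@genes, inferred@genes))
        stop("networks cover different gene universes", call. = FALSE)
    key <- function(e) {
        if (nrow(e) == 0L) return(character(0))
        if (undirected) {
            lo <- pmin(e[, 1L], e[, 2L])
            hi <- pmax(e[, 1L], e[, 2L])
            unique(paste(lo, hi, sep = "\r"))
        } else paste(e[, 1L], e[, 2L], sep = "\r")
    }
    tk <- key(trueNet@edges)
    ik <- key(inferred@edges)
    c(Ce = length(intersect(tk, ik)),
      Me = length(setdiff(tk, ik)),
      Fe = length(setdiff(ik, tk)))
}

#' Precision and recall from confusion counts
#'
#' P = Ce / (Ce + Fe) and R = Ce / (Ce + Me).  Degenerate denominators
#' follow the conventions P = 1 when nothing was inferred (no false
#' assertions) and R = 1 when the reference network is empty, so sweeps
#' over many prefixes stay total; the recall/precision ratio is reported
#' when P > 0 and \code{NA} otherwise.
#'
#' @param counts named vector from \code{\link{confusionCounts}}, or the
#'   Ce count if \code{Me}/\code{Fe} are given separately.
#' @param Me,Fe missed and spurious edge counts (when \code{counts} is a
#'   single number).
#' @return one-row data.frame with columns \code{Ce}, \code{Me},
#'   \code{Fe}, \code{precision}, \code{recall}, \code{ratio}.
#' @examples
#' precisionRecall(3, Me = 0, Fe = 9)$precision   # 0.25
#' precisionRecall(1, Me = 0, Fe = 6)$precision   # 0.142857...
#' @export
precisionRecall <- function(counts, Me = NULL, Fe = NULL) {
    if (!is.null(Me) || !is.null(Fe))
        counts <- c(Ce = as.numeric(counts), Me = as.numeric(Me),
                    Fe = as.numeric(Fe))
    ce <- counts[["Ce"]]; me <- counts[["Me"]]; fe <- counts[["Fe"]]
    if (any(c(ce, me, fe) < 0))
        stop("confusion counts must be non-negative", call. = FALSE)
    p <- if (ce + fe == 0) 1 else ce / (ce + fe)
    r <- if (ce + me == 0) 1 else ce / (ce + me)
    data.frame(Ce = ce, Me = me, Fe = fe, precision = p, recall = r,
               ratio = if (p > 0) r / p else NA_real_)
}

.runInference <- function(bm, method, timeLagged, ...) {
    switch(method,
           mdl = inferMDL(bm, timeLagged = timeLagged, ...),
           pmdl = inferPMDL(bm, timeLagged = timeLagged, ...),
           stop("unknown method '", method, "'", call. = FALSE))
}

#' Data-size saturation sweep
#'
#' Runs an inference algorithm on growing prefixes of a time course
#' (first \code{start} points, then \code{start + step}, ...) and scores
#' each inferred network against the reference.  The recall/precision
#' ratio as a function of the prefix length locates the data size beyond
#' which accuracy stops improving (the saturation point).
#'
#' @param bm full \code{\link{BinaryExpressionSeries}} (>= \code{start}
#'   time points).
#' @param trueNet reference \code{\link{GeneNetwork}}.
#' @param method \code{"pmdl"} (default) or \code{"mdl"}.
#' @param timeLagged use time-lagged metrics (default \code{FALSE}).
#' @param start first prefix length (default 15).
#' @param step prefix increment (default 5).
#' @param ... further arguments to \code{\link{inferMDL}} /
#'   \code{\link{inferPMDL}}.
#' @return data.frame with one row per prefix: \code{mUsed},
#'   \code{nEdges}, \code{Ce}, \code{Me}, \code{Fe}, \code{precision},
#'   \code{recall}, \code{ratio}.
#' @export
saturationSweep <- function(bm, trueNet, method = c("pmdl", "mdl"),
                            timeLagged = FALSE, start = 15L, step = 5L,
                            ...) {
    stopifnot(is(bm, "BinaryExpressionSeries"))
    method <- match.arg(method)
    m <- ncol(bm@values)
    if (m < start)
        stop(sprintf("series has %d < %d time points", m, start),
             call. = FALSE)
    sizes <- seq.int(start, m, by = step)
    rows <- lapply(sizes, function(mu) {
        sub <- BinaryExpressionSeries(bm@values[, seq_len(mu), drop = FALSE])
        fit <- .runInference(sub, method, timeLagged, ...)
        pr <- precisionRecall(confusionCounts(trueNet, inferredNetwork(fit)))
        cbind(data.frame(mUsed = mu, nEdges = nEdges(inferredNetwork(fit))),
              pr)
    })
    do.call(rbind, rows)
}

#' Mutual-information saturation curve study
#'
#' For each prefix length, averages the per-gene entropy, the pairwise
#' conditional entropy H(A|B) = H(A,B) - H(B) and the pairwise mutual
#' information over all ordered gene pairs of the prefix.  On noisy
#' Boolean dynamics the entropies drift toward 1 bit with growing data
#' while the mean MI decays toward 0 -- the saturation phenomenon that
#' motivates lag-trimmed metrics.
#'
#' @param bm a \code{\link{BinaryExpressionSeries}}.
#' @param prefixLengths integer vector of prefix lengths (each <= m).
#' @return data.frame with columns \code{m}, \code{meanEntropy},
#'   \code{meanCondEntropy}, \code{meanMI}.
#' @export
miCurveStudy <- function(bm, prefixLengths) {
    stopifnot(is(bm, "BinaryExpressionSeries"))
    v <- bm@values
    if (any(prefixLengths < 1L | prefixLengths > ncol(v)))
        stop("prefix lengths must lie in [1, m]", call. = FALSE)
    n <- nrow(v)
    rows <- lapply(as.integer(prefixLengths), function(L) {
        sub <- v[, seq_len(L), drop = FALSE]
        hs <- apply(sub, 1L, binaryEntropy)
        ce <- mi <- numeric(0)
        for (i in seq_len(n)) {
            for (j in seq_len(n)) {
                if (i == j) next
                hj <- jointEntropy(sub[i, ], sub[j, ])
                ce <- c(ce, hj - hs[j])
                mi <- c(mi, max(hs[i] + hs[j] - hj, 0))
            }
        }
        data.frame(m = L, meanEntropy = mean(hs), meanCondEntropy = mean(ce),
                   meanMI = mean(mi))
    })
    do.call(rbind, rows)
}
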