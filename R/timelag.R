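# Event-based regulatory time lags on binary expression profiles.
# All indices are 1-based time points; the series must be equally spaced.

#' Time point of a gene's initial up-regulation
#'
#' The first time point at which the gene switches ON: the smallest t >= 2
#' with x(t-1) = 0 and x(t) = 1.  A gene that is already ON at the first
#' time point is taken to up-regulate at t = 1 (no observable 0 -> 1
#' transition exists, but a regulator active from the start should not be
#' discarded).  Returns \code{NA} for a gene that is never ON.
#'
#' @param x 0/1 vector (one gene's binary time course).
#' @return integer time point, or \code{NA_integer_}.
#' @examples
#' initialUpregulationTime(c(0, 1, 0, 0, 0, 1))  # 2
#' initialUpregulationTime(c(1, 0, 0, 1))        # 1 (starts ON)
#' @export
initialUpregulationTime <- function(x) {
    x <- .checkBinarySeq(x)
    if (x[1L] == 1L)
        return(1L)
    up <- which(x[-1L] == 1L & x[-length(x)] == 0L)
    if (length(up)) up[1L] + 1L else NA_integer_
}

#' First expression change after a given time point
#'
#' The smallest t > t0 at which the gene's binary state differs from its
#' state at t - 1 (any flip, in either direction), or \code{NA} if the
#' gene never changes again.
#'
#' @param x 0/1 vector of length m.
#' @param t0 time point in [1, m].
#' @return integer time point, or \code{NA_integer_}.
#' @export
firstChangeAfter <- function(x, t0) {
    x <- .checkBinarySeq(x)
    t0 <- as.integer(t0)
    if (is.na(t0) || t0 < 1L || t0 > length(x))
        stop("'t0' must lie in [1, ", length(x), "]", call. = FALSE)
    chg <- which(x[-1L] != x[-length(x)]) + 1L
    chg <- chg[chg > t0]
    if (length(chg)) chg[1L] else NA_integer_
}

#' Non-negative regulatory time lag from A to B
#'
#' The lag tau(A -> B) is the time from A's initial up-regulation to B's
#' first subsequent expression change.  A gene is assumed able to affect
#' another only while it is ON, so the reference event on the regulator
#' side is its switch to the ON state; by construction the lag is always
#' >= 1, avoiding the negative lags that arise when lags are differenced
#' from both genes' initial-change times (see \code{\link{zouLag}}).
#'
#' @param a regulator 0/1 vector.
#' @param b target 0/1 vector of the same length.
#' @return positive integer lag in time points, or \code{NA_integer_} when
#'   A never up-regulates or B never changes afterwards.
#' @examples
#' a <- c(0, 1, 1, 1, 1, 0, 0)  # up-regulates at t = 2
#' b <- c(0, 0, 1, 1, 1, 1, 1)  # first change after t = 2 is at t = 3
#' proposedLag(a, b)  # 1
#' @export
proposedLag <- function(a, b) {
    .checkSameLength(a, b)
    ua <- initialUpregulationTime(a)
    if (is.na(ua))
        return(NA_integer_)
    cb <- firstChangeAfter(b, ua)
    if (is.na(cb))
        return(NA_integer_)
    cb - ua
}

#' Initial-change-difference lag (possibly negative)
#'
#' The classical lag definition: the target's initial expression change
#' time minus the regulator's.  Whenever the two genes first change at
#' different time points, one direction of every pair comes out negative,
#' which is why \code{\link{proposedLag}} replaces it for building lag
#' matrices; this version is provided for comparison.
#'
#' @param a regulator 0/1 vector.
#' @param b target 0/1 vector of the same length.
#' @return integer lag (may be negative or zero).
#' @export
zouLag <- function(a, b) {
    a <- .checkBinarySeq(a, "a")
    b <- .checkBinarySeq(b, "b")
    .checkSameLength(a, b)
    ia <- firstChangeAfter(a, 1L)
    ib <- firstChangeAfter(b, 1L)
    if (is.na(ia) || is.na(ib))
        stop("initial expression change undefined for a constant gene",
             call. = FALSE)
    ib - ia
}

#' Pairwise lag matrix for a binary expression series
#'
#' Computes \code{\link{proposedLag}} for every ordered gene pair.  Pairs
#' whose lag is undefined (regulator never ON, or target never changes
#' after the regulator's up-regulation), or whose lag would leave fewer
#' than \code{minOverlap} overlapping time points, receive
#' \code{defaultTau} and are flagged as fallbacks.
#'
#' @param bm a \code{\link{BinaryExpressionSeries}}.
#' @param defaultTau positive integer substituted for undefined/oversized
#'   lags; 1 recovers the conventional unit-delay behaviour.
#' @param minOverlap minimum overlap (time points) any lag must leave.
#' @return a \code{\link{LagMatrix}}.
#' @export
computeLagMatrix <- function(bm, defaultTau = 1L, minOverlap = 4L) {
    stopifnot(is(bm, "BinaryExpressionSeries"))
    defaultTau <- as.integer(defaultTau)
    minOverlap <- as.integer(minOverlap)
    v <- bm@values
    n <- nrow(v)
    m <- ncol(v)
    if (defaultTau < 1L || m - defaultTau < minOverlap)
        stop("'defaultTau' must be >= 1 and leave at least 'minOverlap' points",
             call. = FALSE)
    ids <- rownames(v)
    tau <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
    fb <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (i == j) next
            lag <- proposedLag(v[i, ], v[j, ])
            if (is.na(lag) || m - lag < minOverlap) {
                tau[i, j] <- defaultTau
                fb[i, j] <- TRUE
            } else {
                tau[i, j] <- lag
            }
        }
    }
    new("LagMatrix", tau = tau, fallback = fb)
}

#' A unit lag matrix (tau = 1 everywhere)
#'
#' Convenience constructor for the legacy unit-delay mode in which every
#' ordered pair is assigned a lag of one time point.
#'
#' @param geneIds character vector of gene ids.
#' @return a \code{\link{LagMatrix}} with all off-diagonal lags 1 and no
#'   fallback flags.
#' @export
unitLagMatrix <- function(geneIds) {
    n <- length(geneIds)
    tau <- matrix(1L, n, n, dimnames = list(geneIds, geneIds))
    diag(tau) <- NA_integer_
    fb <- matrix(FALSE, n, n, dimnames = list(geneIds, geneIds))
    new("LagMatrix", tau = tau, fallback = fb)
}
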