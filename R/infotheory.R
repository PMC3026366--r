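# Plug-in (maximum-likelihood) entropies on binary sequences, in bits.
# No pseudocounts here: smoothing belongs to the code-length estimators,
# not to the information metrics themselves.

.NEG_EPS <- 1e-12

.checkBinarySeq <- function(x, what = "sequence") {
    if (length(x) < 1L)
        stop(what, " must be non-empty", call. = FALSE)
    if (anyNA(x) || !all(x == 0L | x == 1L))
        stop(what, " must contain only 0/1 symbols", call. = FALSE)
    invisible(as.integer(x))
}

.checkSameLength <- function(...) {
    ls <- lengths(list(...))
    if (length(unique(ls)) != 1L)
        stop("sequences must have equal length (got ",
             paste(ls, collapse = ", "), ")", call. = FALSE)
}

# -sum(p log2 p) over a vector of counts, with 0 log 0 = 0
.entropyFromCounts <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
}

.clampNonNeg <- function(x, what) {
    if (x < -.NEG_EPS)
        stop("internal consistency error: ", what, " = ", x,
             " is negative beyond tolerance", call. = FALSE)
    max(x, 0)
}

#' Empirical entropy of a binary sequence
#'
#' Entropy of the ON/OFF states a gene takes over the time course,
#' H = -p0 log2 p0 - p1 log2 p1, with the empirical symbol frequencies as
#' plug-in probabilities and the convention 0 log 0 = 0.  For a binary
#' alphabet the result lies in [0, 1] bits.
#'
#' @param a integer/numeric vector of 0/1 symbols, length >= 1.
#' @return entropy in bits.
#' @examples
#' binaryEntropy(c(0, 0, 1, 1))  # 1 bit
#' binaryEntropy(c(0, 1, 1, 1))  # 0.811 bits
#' @export
binaryEntropy <- function(a) {
    a <- .checkBinarySeq(a)
    .entropyFromCounts(c(sum(a == 0L), sum(a == 1L)))
}

#' Joint entropy of two or three binary sequences
#'
#' The sequences are treated as a single vector-valued variable; the joint
#' entropy is the plug-in entropy over the 4 (pairwise) or 8 (three-way)
#' joint symbol cells.
#'
#' @param a,b,c equal-length 0/1 vectors; \code{c} is optional.
#' @return joint entropy in bits.
#' @export
jointEntropy <- function(a, b, c = NULL) {
    a <- .checkBinarySeq(a, "a")
    b <- .checkBinarySeq(b, "b")
    if (is.null(c)) {
        .checkSameLength(a, b)
        .entropyFromCounts(tabulate(1L + a + 2L * b, nbins = 4L))
    } else {
        c <- .checkBinarySeq(c, "c")
        .checkSameLength(a, b, c)
        .entropyFromCounts(tabulate(1L + a + 2L * b + 4L * c, nbins = 8L))
    }
}

#' Mutual information between two binary sequences
#'
#' MI(A;B) = H(A) + H(B) - H(A,B) on the empirical joint distribution;
#' tiny negative floating-point results are clamped to zero.  MI is
#' symmetric in its arguments and bounded by min(H(A), H(B)).
#'
#' @param a,b equal-length 0/1 vectors.
#' @return mutual information in bits (>= 0).
#' @export
mutualInformation <- function(a, b) {
    .checkSameLength(a, b)
    .clampNonNeg(binaryEntropy(a) + binaryEntropy(b) - jointEntropy(a, b),
                 "MI")
}

#' Conditional mutual information between binary sequences
#'
#' CMI(A;B|C) = H(A,C) + H(B,C) - H(C) - H(A,B,C): the residual dependence
#' between A and B once C is accounted for.  High MI between two genes may
#' reflect an indirect route through a third; CMI close to zero given that
#' third gene flags the pair as indirectly linked.
#'
#' @param a,b,c equal-length 0/1 vectors.
#' @return conditional mutual information in bits (>= 0 after clamping).
#' @export
conditionalMutualInformation <- function(a, b, c) {
    .checkSameLength(a, b, c)
    .clampNonNeg(jointEntropy(a, c) + jointEntropy(b, c) -
                 binaryEntropy(c) - jointEntropy(a, b, c), "CMI")
}

#' Trim a sequence pair to a regulatory lag
#'
#' For a lag of tau time points from regulator A to target B, drops the
#' last tau symbols of A and the first tau symbols of B, aligning each
#' regulator state with the target state tau steps later.  Both returned
#' sequences have length m - tau.
#'
#' @param a regulator-side 0/1 vector of length m.
#' @param b target-side 0/1 vector of length m.
#' @param tau non-negative integer lag, in time points.
#' @param minOverlap smallest admissible trimmed length (default 1; the
#'   lagged metrics enforce their own stricter floor).
#' @return list with elements \code{a} and \code{b}, the trimmed pair.
#' @examples
#' lagTrimPair(c(0, 1, 0, 1), c(1, 1, 0, 0), 1)
#' @export
lagTrimPair <- function(a, b, tau, minOverlap = 1L) {
    a <- .checkBinarySeq(a, "a")
    b <- .checkBinarySeq(b, "b")
    .checkSameLength(a, b)
    m <- length(a)
    tau <- as.integer(tau)
    if (tau < 0L)
        stop("'tau' must be non-negative", call. = FALSE)
    if (tau >= m || m - tau < minOverlap)
        stop(sprintf("lag %d leaves %d < %d overlapping time points",
                     tau, m - tau, max(minOverlap, 1L)), call. = FALSE)
    if (tau == 0L)
        return(list(a = a, b = b))
    list(a = a[seq_len(m - tau)], b = b[(tau + 1L):m])
}

#' Time-lagged mutual information (TLMI)
#'
#' Mutual information between a regulator and its target evaluated over the
#' lag-aligned window: the regulator's last tau symbols and the target's
#' first tau symbols are discarded before computing MI.  Unlike plain MI,
#' TLMI is not symmetric, because the two directions generally carry
#' different lags.  With tau = 0 it reduces to MI exactly.
#'
#' @param a regulator 0/1 vector.
#' @param b target 0/1 vector of the same length m.
#' @param tau non-negative integer lag.
#' @param minOverlap minimum trimmed length required (default 4); with
#'   fewer remaining points the binary MI estimate is mostly noise.
#' @return TLMI in bits.
#' @export
tlmi <- function(a, b, tau, minOverlap = 4L) {
    tp <- lagTrimPair(a, b, tau, minOverlap)
    mutualInformation(tp$a, tp$b)
}

#' Time-lagged conditional mutual information (TLCMI)
#'
#' CMI between regulator A and target B given a third gene C, on the
#' lag-aligned window for lag tau: the last tau symbols are deleted from A
#' and C (both viewed from the regulator side) and the first tau symbols
#' from B.  With tau = 0 it reduces to CMI.
#'
#' @param a regulator 0/1 vector.
#' @param b target 0/1 vector.
#' @param c conditioning 0/1 vector (trimmed on the regulator side).
#' @param tau non-negative integer lag.
#' @param minOverlap minimum trimmed length required (default 4).
#' @return TLCMI in bits.
#' @export
tlcmi <- function(a, b, c, tau, minOverlap = 4L) {
    c <- .checkBinarySeq(c, "c")
    .checkSameLength(a, b, c)
    tp <- lagTrimPair(a, b, tau, minOverlap)
    m <- length(c)
    cTrim <- if (tau > 0L) c[seq_len(m - as.integer(tau))] else c
    conditionalMutualInformation(tp$a, tp$b, cTrim)
}
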