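# Preprocessing of continuous time-series expression: neighbour-mean
# imputation of missing time points, then rank-based binary quantization.

#' Impute missing time points by neighbour means
#'
#' An interior missing value is set to the mean of its two temporal
#' neighbours; a missing first or last time point is set to the nearest
#' observed value.  Runs of two or more consecutive interior gaps are
#' filled left to right, each gap using the already-filled value on its
#' left and the nearest observed value on its right (for a single gap this
#' is exactly the two-neighbour mean).  Observed cells are never altered.
#'
#' @param expr an \code{\link{ExpressionSeries}} (possibly with \code{NA}s).
#' @return an \code{ExpressionSeries} with no missing values.
#' @examples
#' m <- rbind(G1 = c(1, NA, 3), G2 = c(NA, 2, 3))
#' exprValues(imputeMissing(ExpressionSeries(m)))
#' @export
imputeMissing <- function(expr) {
    stopifnot(is(expr, "ExpressionSeries"))
    v <- expr@values
    m <- ncol(v)
    for (g in seq_len(nrow(v))) {
        x <- v[g, ]
        if (!anyNA(x)) next
        obs <- which(!is.na(x))
        if (length(obs) == 0L)
            stop(sprintf("gene '%s' has no observed values", rownames(v)[g]),
                 call. = FALSE)
        for (t in seq_len(m)) {
            if (!is.na(x[t])) next
            rightObs <- obs[obs > t]
            if (t == 1L) {
                x[t] <- x[rightObs[1L]]          # leading gap: nearest observed
            } else if (length(rightObs) == 0L) {
                x[t] <- x[t - 1L]                # trailing gap: nearest value
            } else {
                x[t] <- (x[t - 1L] + x[rightObs[1L]]) / 2
            }
        }
        v[g, ] <- x
    }
    ExpressionSeries(v)
}

#' Quantize a continuous expression series to ON/OFF states
#'
#' Per gene: the m values are sorted in ascending order, the first and
#' last sorted values are discarded as outliers (exactly one cell each,
#' even under ties), and the median of the remaining values becomes the
#' gene's threshold.  Every original value strictly above the threshold
#' maps to 1 (ON), everything else -- including the two trimmed extremes
#' and values tied with the threshold -- maps to 0 (OFF).  The rule is
#' rank-based, so any strictly monotone rescaling of a gene's profile
#' yields the same binary row.  A constant gene has no informative split
#' and becomes all 0 with a warning.
#'
#' @param expr an \code{\link{ExpressionSeries}} with no missing values
#'   (run \code{\link{imputeMissing}} first) and at least 4 time points,
#'   so that outlier trimming leaves values to take a median over.
#' @param assumeBinary if \code{TRUE}, require the input to be strictly
#'   0/1-valued already and skip quantization (for data simulated in the
#'   Boolean regime).
#' @return a \code{\link{BinaryExpressionSeries}}.
#' @examples
#' m <- rbind(G1 = c(1, 2, 3, 4, 5, 6), G2 = c(6, 5, 4, 3, 2, 1))
#' exprValues(binarize(ExpressionSeries(m)))
#' @export
binarize <- function(expr, assumeBinary = FALSE) {
    stopifnot(is(expr, "ExpressionSeries"))
    v <- expr@values
    if (anyNA(v))
        stop("missing values present; run imputeMissing() first", call. = FALSE)
    if (assumeBinary) {
        if (!all(v %in% c(0, 1)))
            stop("assumeBinary = TRUE but values are not strictly 0/1",
                 call. = FALSE)
        return(BinaryExpressionSeries(v))
    }
    if (ncol(v) < 4L)
        stop("need at least 4 time points to trim outliers and quantize",
             call. = FALSE)
    out <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
    for (g in seq_len(nrow(v))) {
        x <- v[g, ]
        if (max(x) == min(x)) {
            warning(sprintf("gene '%s' is constant; quantized to all-OFF",
                            rownames(v)[g]), call. = FALSE)
            next
        }
        s <- sort(x)
        thr <- stats::median(s[2:(length(s) - 1L)])
        out[g, ] <- as.integer(x > thr)
    }
    BinaryExpressionSeries(out)
}
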