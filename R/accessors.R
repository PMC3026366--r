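#' @rdname geneIds
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Gene identifiers of an object
#'
#' @param x an \code{ExpressionSeries}, \code{BinaryExpressionSeries},
#'   \code{GeneNetwork}, \code{LagMatrix} or \code{BooleanNetworkModel}.
#' @return character vector of gene ids, in storage order.
#' @export
setMethod("geneIds", "ExpressionSeries", function(x) rownames(x@values))

#' @rdname geneIds
#' @export
setMethod("geneIds", "BinaryExpressionSeries", function(x) rownames(x@values))

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneNetwork", function(x) x@genes)

#' @rdname geneIds
#' @export
setMethod("geneIds", "LagMatrix", function(x) rownames(x@tau))

#' @rdname geneIds
#' @export
setMethod("geneIds", "BooleanNetworkModel", function(x) x@genes)

#' @rdname exprValues
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Expression value matrix
#'
#' @param x an \code{ExpressionSeries} or \code{BinaryExpressionSeries}.
#' @return the underlying genes x time-points matrix (continuous with
#'   \code{NA} for missing cells, or integer 0/1).
#' @export
setMethod("exprValues", "ExpressionSeries", function(x) x@values)

#' @rdname exprValues
#' @export
setMethod("exprValues", "BinaryExpressionSeries", function(x) x@values)

#' @rdname nTimePoints
#' @export
setGeneric("nTimePoints", function(x) standardGeneric("nTimePoints"))

#' Number of time points
#'
#' @param x an \code{ExpressionSeries} or \code{BinaryExpressionSeries}.
#' @return integer count of (equally spaced) time points.
#' @export
setMethod("nTimePoints", "ExpressionSeries", function(x) ncol(x@values))

#' @rdname nTimePoints
#' @export
setMethod("nTimePoints", "BinaryExpressionSeries", function(x) ncol(x@values))

#' Missing-value mask of a continuous expression series
#'
#' @param x an \code{ExpressionSeries}.
#' @return logical matrix, \code{TRUE} where the observation is missing.
#' @export
missingMask <- function(x) {
    stopifnot(is(x, "ExpressionSeries"))
    is.na(x@values)
}

#' Edge table of a network
#'
#' @param x a \code{GeneNetwork}.
#' @return data.frame with character columns \code{from} and \code{to},
#'   one row per directed edge.
#' @export
networkEdges <- function(x) {
    stopifnot(is(x, "GeneNetwork"))
    data.frame(from = x@edges[, 1L], to = x@edges[, 2L],
               stringsAsFactors = FALSE)
}

#' Number of edges in a network
#'
#' @param x a \code{GeneNetwork}.
#' @return integer edge count.
#' @export
nEdges <- function(x) {
    stopifnot(is(x, "GeneNetwork"))
    nrow(x@edges)
}

#' Lag values and fallback flags
#'
#' @param x a \code{LagMatrix}.
#' @return \code{lagValues}: the integer matrix of pairwise lags
#'   (regulator rows, target columns, diagonal \code{NA});
#'   \code{lagFallback}: the logical matrix flagging substituted defaults.
#' @export
lagValues <- function(x) {
    stopifnot(is(x, "LagMatrix"))
    x@tau
}

#' @rdname lagValues
#' @export
lagFallback <- function(x) {
    stopifnot(is(x, "LagMatrix"))
    x@fallback
}

#' Components of an inference result
#'
#' @param x a \code{GRNInference}.
#' @return \code{inferredNetwork}: the final \code{GeneNetwork};
#'   \code{sweepTrace}: the per-threshold description-length trace;
#'   \code{chosenThreshold}: the winning threshold in bits.
#' @export
inferredNetwork <- function(x) {
    stopifnot(is(x, "GRNInference"))
    x@network
}

#' @rdname inferredNetwork
#' @export
sweepTrace <- function(x) {
    stopifnot(is(x, "GRNInference"))
    x@trace
}

#' @rdname inferredNetwork
#' @export
chosenThreshold <- function(x) {
    stopifnot(is(x, "GRNInference"))
    x@threshold
}

setMethod("show", "ExpressionSeries", function(object) {
    v <- object@values
    cat(sprintf("ExpressionSeries: %d genes x %d time points (%d missing cells)\n",
                nrow(v), ncol(v), sum(is.na(v))))
})

setMethod("show", "BinaryExpressionSeries", function(object) {
    v <- object@values
    cat(sprintf("BinaryExpressionSeries: %d genes x %d time points (%.1f%% ON)\n",
                nrow(v), ncol(v), 100 * mean(v)))
})

setMethod("show", "GeneNetwork", function(object) {
    cat(sprintf("GeneNetwork: %d genes, %d directed edges\n",
                length(object@genes), nrow(object@edges)))
})

setMethod("show", "LagMatrix", function(object) {
    off <- object@tau[row(object@tau) != col(object@tau)]
    cat(sprintf("LagMatrix: %d genes; lag range [%d, %d], %d/%d pairs on fallback\n",
                nrow(object@tau), min(off), max(off),
                sum(object@fallback[row(object@fallback) != col(object@fallback)]),
                length(off)))
})

setMethod("show", "BooleanNetworkModel", function(object) {
    cat(sprintf("BooleanNetworkModel: %d genes, %d regulatory inputs, flip noise %.3g\n",
                length(object@genes), sum(lengths(object@parents)), object@noise))
})

setMethod("show", "GRNInference", function(object) {
    cat(sprintf("GRNInference (%s): %d edges at threshold %.4g bits (%d candidates swept)\n",
                object@method, nrow(object@network@edges), object@threshold,
                nrow(object@trace)))
})
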