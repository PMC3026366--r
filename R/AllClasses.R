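#' @import methods
NULL

#' Continuous time-series expression matrix
#'
#' Holds a genes x time-points grid of expression values on an arbitrary
#' continuous scale, sampled at equally spaced time points.  Missing
#' observations are encoded as \code{NA}; \code{\link{imputeMissing}} fills
#' them and \code{\link{binarize}} quantizes the matrix to ON/OFF calls.
#'
#' @slot values numeric matrix, one row per gene (rownames are the unique
#'   gene identifiers) and one column per time point, in temporal order.
#'   \code{NA} marks a missing observation.
#'
#' @seealso \code{\link{readExpressionTSV}}, \code{\link{binarize}}
#' @export
setClass("ExpressionSeries", representation(values = "matrix"))

setValidity("ExpressionSeries", function(object) {
    v <- object@values
    if (!is.numeric(v))
        return("'values' must be a numeric matrix")
    if (nrow(v) < 2L || ncol(v) < 2L)
        return("need at least 2 genes and 2 time points")
    ids <- rownames(v)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
        return("every gene needs a non-empty identifier (rownames)")
    if (anyDuplicated(ids))
        return(sprintf("duplicate gene id '%s'", ids[duplicated(ids)][1L]))
    TRUE
})

#' Binary (ON/OFF) time-series expression matrix
#'
#' A genes x time-points grid over \{0, 1\}, where 1 means the gene is
#' up-regulated (ON) and 0 down-regulated (OFF).  This is the substrate of
#' every information-theoretic computation in the package: each row is the
#' binary sequence of states a gene traverses over the time course.
#'
#' @slot values integer matrix of 0/1 values with unique gene identifiers
#'   as rownames; no missing values are allowed.
#'
#' @seealso \code{\link{binarize}}, \code{\link{simulateSeries}}
#' @export
setClass("BinaryExpressionSeries", representation(values = "matrix"))

setValidity("BinaryExpressionSeries", function(object) {
    v <- object@values
    if (nrow(v) < 2L || ncol(v) < 2L)
        return("need at least 2 genes and 2 time points")
    ids <- rownames(v)
    if (is.null(ids) || anyDuplicated(ids))
        return("gene ids (rownames) must be present and unique")
    if (anyNA(v) || !all(v %in% c(0L, 1L)))
        return("all cells must be 0 or 1 with no missing values")
    TRUE
})

#' Directed gene network
#'
#' A directed graph over a fixed gene universe; an edge regulator -> target
#' asserts that the regulator controls the target's expression.  Used both
#' for inference output and as evaluation ground truth.  Self-loops are
#' disallowed: the mutual information of a gene with itself is its entropy
#' and would trivially pass any threshold.
#'
#' @slot genes character vector of unique gene identifiers (the universe).
#' @slot edges two-column character matrix (columns \code{from}, \code{to}),
#'   one row per directed edge; endpoints must belong to \code{genes}.
#'
#' @seealso \code{\link{readNetwork}}, \code{\link{writeNetwork}}
#' @export
setClass("GeneNetwork",
         representation(genes = "character", edges = "matrix"))

setValidity("GeneNetwork", function(object) {
    g <- object@genes
    e <- object@edges
    if (length(g) == 0L || anyDuplicated(g))
        return("gene universe must be non-empty with unique ids")
    if (ncol(e) != 2L)
        return("'edges' must have two columns (from, to)")
    if (nrow(e)) {
        if (!all(e %in% g))
            return("edge endpoints must belong to the gene universe")
        if (any(e[, 1L] == e[, 2L]))
            return("self-loops are not allowed")
        if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\r")))
            return("duplicate edges are not allowed")
    }
    TRUE
})

#' Pairwise regulatory time lags
#'
#' Stores the estimated regulatory delay tau(i -> j), in time points, for
#' every ordered gene pair, together with a flag marking pairs where the
#' event-based lag was undefined (or left too little sequence overlap) and
#' the configured default was substituted.
#'
#' @slot tau integer matrix of non-negative lags; rows are regulators,
#'   columns targets, diagonal is \code{NA} (unused).
#' @slot fallback logical matrix of the same shape; \code{TRUE} where the
#'   default lag was substituted for an undefined or oversized lag.
#'
#' @seealso \code{\link{computeLagMatrix}}, \code{\link{proposedLag}}
#' @export
setClass("LagMatrix",
         representation(tau = "matrix", fallback = "matrix"))

setValidity("LagMatrix", function(object) {
    tt <- object@tau
    fb <- object@fallback
    if (!identical(dim(tt), dim(fb)) || nrow(tt) != ncol(tt))
        return("'tau' and 'fallback' must be square matrices of equal shape")
    off <- tt[row(tt) != col(tt)]
    if (anyNA(off) || any(off < 0L))
        return("off-diagonal lags must be non-negative and defined")
    TRUE
})

#' Boolean network model
#'
#' A synchronous Boolean network: each gene carries a parent set, a complete
#' truth table over its parents' states and a per-parent regulatory delay.
#' Genes with no parents are treated as exogenous inputs and sampled
#' independently at every step, which keeps the network dynamically driven
#' (mirroring the external conditions that drive curated in-silico modules).
#'
#' @slot genes character vector of gene identifiers.
#' @slot parents list (one element per gene) of integer vectors of parent
#'   indices; possibly empty.
#' @slot tables list of integer 0/1 vectors of length \code{2^k} giving each
#'   gene's update rule; entry \code{1 + sum(bit_i * 2^(i-1))} is looked up.
#' @slot delays list of positive integer vectors, one delay per parent, in
#'   time points (1 = the conventional unit delay).
#' @slot noise numeric in [0, 0.5): per-step, per-gene probability that the
#'   updated symbol is flipped.
#'
#' @seealso \code{\link{randomBooleanNetwork}}, \code{\link{simulateSeries}}
#' @export
setClass("BooleanNetworkModel",
         representation(genes = "character", parents = "list",
                        tables = "list", delays = "list", noise = "numeric"))

setValidity("BooleanNetworkModel", function(object) {
    n <- length(object@genes)
    if (n < 2L || anyDuplicated(object@genes))
        return("need >= 2 uniquely named genes")
    if (length(object@parents) != n || length(object@tables) != n ||
        length(object@delays) != n)
        return("'parents', 'tables' and 'delays' must have one entry per gene")
    for (j in seq_len(n)) {
        k <- length(object@parents[[j]])
        if (k && (anyDuplicated(object@parents[[j]]) ||
                  any(object@parents[[j]] == j)))
            return(sprintf("gene %d: parents must be distinct and exclude itself", j))
        if (length(object@tables[[j]]) != 2^k)
            return(sprintf("gene %d: truth table must have 2^%d entries", j, k))
        if (!all(object@tables[[j]] %in% c(0L, 1L)))
            return(sprintf("gene %d: truth table entries must be 0/1", j))
        if (length(object@delays[[j]]) != k || (k && any(object@delays[[j]] < 1L)))
            return(sprintf("gene %d: one positive delay per parent required", j))
    }
    if (object@noise < 0 || object@noise >= 0.5)
        return("'noise' must lie in [0, 0.5)")
    TRUE
})

#' Network inference result
#'
#' The outcome of an MDL or PMDL threshold sweep: the selected network, the
#' winning score threshold, and the full trace of candidate models with
#' their description-length components.  For PMDL runs the network retained
#' by threshold selection before CMI pruning is kept alongside the final
#' (pruned) network.
#'
#' @slot network \code{GeneNetwork}; the final inferred network.
#' @slot prePruneNetwork \code{GeneNetwork}; the network selected by the
#'   description-length sweep before any pruning (identical to
#'   \code{network} for MDL runs).
#' @slot threshold numeric; the winning score threshold in bits.
#' @slot trace data.frame with one row per candidate threshold: columns
#'   \code{threshold}, \code{modelBits}, \code{dataBits}, \code{totalBits},
#'   \code{nEdges}.
#' @slot lags \code{LagMatrix} used for the lag-trimmed metrics.
#' @slot method character, one of \code{"mdl"}, \code{"pmdl"}.
#'
#' @seealso \code{\link{inferMDL}}, \code{\link{inferPMDL}}
#' @export
setClass("GRNInference",
         representation(network = "GeneNetwork",
                        prePruneNetwork = "GeneNetwork",
                        threshold = "numeric",
                        trace = "data.frame",
                        lags = "LagMatrix",
                        method = "character"))
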