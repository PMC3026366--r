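#' Construct an ExpressionSeries
#'
#' @param values numeric matrix (genes x time points); \code{NA} marks a
#'   missing observation.
#' @param geneIds optional character vector of gene identifiers; defaults
#'   to existing rownames.
#' @return a validated \code{\link{ExpressionSeries}}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4, dimnames = list(c("G1", "G2", "G3"), NULL))
#' ExpressionSeries(m)
#' @export
ExpressionSeries <- function(values, geneIds = rownames(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    rownames(values) <- geneIds
    colnames(values) <- NULL
    new("ExpressionSeries", values = values)
}

#' Construct a BinaryExpressionSeries
#'
#' @param values matrix of 0/1 values (genes x time points).
#' @param geneIds optional character vector of gene identifiers.
#' @return a validated \code{\link{BinaryExpressionSeries}}.
#' @export
BinaryExpressionSeries <- function(values, geneIds = rownames(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "integer"
    rownames(values) <- geneIds
    colnames(values) <- NULL
    new("BinaryExpressionSeries", values = values)
}

#' Construct a GeneNetwork
#'
#' @param genes character vector: the gene universe.  When omitted it is
#'   taken as the union of edge endpoints.
#' @param edges edge list as a two-column matrix or data.frame
#'   (regulator, target), or \code{NULL} for an edgeless network.
#' @return a validated \code{\link{GeneNetwork}}.
#' @examples
#' GeneNetwork(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' @export
GeneNetwork <- function(genes = NULL, edges = NULL) {
    if (is.null(edges) || NROW(edges) == 0L) {
        e <- matrix(character(0), ncol = 2L)
    } else {
        e <- as.matrix(edges)
        storage.mode(e) <- "character"
        e <- unique(e)
    }
    colnames(e) <- c("from", "to")
    if (is.null(genes))
        genes <- sort(unique(as.character(e)))
    if (nrow(e)) {
        ord <- order(e[, 1L], e[, 2L], method = "radix")
        e <- e[ord, , drop = FALSE]
    }
    new("GeneNetwork", genes = as.character(genes), edges = e)
}
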