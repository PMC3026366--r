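# Plain-text I/O: TSV expression matrices, edge lists and SIF networks.
# Formats are deliberately minimal so that fixtures stay human-readable.

.isMissingToken <- function(tok) tok == "" | toupper(tok) == "NA"

#' Read a genes x time-points expression matrix from TSV
#'
#' Expects one row per gene: the gene identifier in the first column and
#' its expression values at consecutive, equally spaced time points in the
#' remaining columns.  Empty cells or \code{NA} (case-insensitive) mark
#' missing observations; any other non-numeric cell is a parse error.
#'
#' @param path file path.
#' @param hasHeader if \code{TRUE} (default) the first line is a header
#'   and is skipped.
#' @return an \code{\link{ExpressionSeries}}; row order follows the file.
#' @export
readExpressionTSV <- function(path, hasHeader = TRUE) {
    if (!file.exists(path))
        stop("expression file not found: ", path, call. = FALSE)
    lines <- readLines(path)
    lineNo <- seq_along(lines)
    if (hasHeader) {
        lines <- lines[-1L]
        lineNo <- lineNo[-1L]
    }
    keep <- nzchar(lines)
    lines <- lines[keep]
    lineNo <- lineNo[keep]
    if (length(lines) < 2L)
        stop("expression file must contain at least 2 gene rows", call. = FALSE)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    widths <- lengths(fields)
    if (length(unique(widths)) != 1L) {
        bad <- lineNo[which(widths != widths[1L])[1L]]
        stop(sprintf("ragged row at line %d (expected %d columns)",
                     bad, widths[1L]), call. = FALSE)
    }
    if (widths[1L] < 3L)
        stop("fewer than 2 time points in expression file", call. = FALSE)
    ids <- vapply(fields, `[`, character(1L), 1L)
    if (anyDuplicated(ids))
        stop(sprintf("duplicate gene id '%s'", ids[duplicated(ids)][1L]),
             call. = FALSE)
    vals <- matrix(NA_real_, length(ids), widths[1L] - 1L,
                   dimnames = list(ids, NULL))
    for (r in seq_along(fields)) {
        toks <- fields[[r]][-1L]
        miss <- .isMissingToken(toks)
        num <- suppressWarnings(as.numeric(toks))
        bad <- which(!miss & is.na(num))
        if (length(bad))
            stop(sprintf("non-numeric value '%s' at line %d, column %d",
                         toks[bad[1L]], lineNo[r], bad[1L] + 1L),
                 call. = FALSE)
        num[miss] <- NA_real_
        vals[r, ] <- num
    }
    ExpressionSeries(vals)
}

#' Write an expression series to TSV
#'
#' Inverse of \code{\link{readExpressionTSV}}: gene id first, then one
#' column per time point, missing cells written as \code{NA}.  The header
#' line labels time points \code{t1..tm}.
#'
#' @param expr an \code{ExpressionSeries} or \code{BinaryExpressionSeries}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeExpressionTSV <- function(expr, path) {
    v <- exprValues(expr)
    header <- paste(c("gene", paste0("t", seq_len(ncol(v)))), collapse = "\t")
    body <- vapply(seq_len(nrow(v)), function(r) {
        cells <- format(v[r, ], trim = TRUE, digits = 15)
        cells[is.na(v[r, ])] <- "NA"
        paste(c(rownames(v)[r], cells), collapse = "\t")
    }, character(1L))
    writeLines(c(header, body), path)
    invisible(path)
}

#' Write a gene network to an edge-list or SIF file
#'
#' Edges are written sorted lexicographically by (regulator, target).  The
#' \code{edgelist} dialect is one \code{regulator<TAB>target} line per
#' edge; the \code{sif} dialect inserts the interaction label
#' \code{regulates} as a middle column.  An empty network produces an
#' empty, header-free file.
#'
#' @param net a \code{\link{GeneNetwork}}.
#' @param path output file path.
#' @param format \code{"edgelist"} (default) or \code{"sif"}.
#' @return invisibly, \code{path}.
#' @export
writeNetwork <- function(net, path, format = c("edgelist", "sif")) {
    stopifnot(is(net, "GeneNetwork"))
    format <- match.arg(format)
    e <- net@edges
    if (nrow(e)) {
        ord <- order(e[, 1L], e[, 2L], method = "radix")
        e <- e[ord, , drop = FALSE]
    }
    lines <- if (nrow(e) == 0L) character(0)
             else if (format == "edgelist") paste(e[, 1L], e[, 2L], sep = "\t")
             else paste(e[, 1L], "regulates", e[, 2L], sep = "\t")
    writeLines(lines, path)
    invisible(path)
}

#' Read a gene network from an edge-list or SIF file
#'
#' Accepts two-column \code{regulator<TAB>target} lines or three-column
#' SIF lines (\code{regulator<TAB>relation<TAB>target}); the dialect is
#' detected per file.  Self-loops are rejected.  Unless \code{genes} is
#' supplied, the gene universe is the sorted union of edge endpoints.
#'
#' @param path file path.
#' @param genes optional explicit gene universe.
#' @return a \code{\link{GeneNetwork}}.
#' @export
readNetwork <- function(path, genes = NULL) {
    if (!file.exists(path))
        stop("network file not found: ", path, call. = FALSE)
    lines <- readLines(path)
    keep <- nzchar(lines)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    lineNo <- which(keep)
    edges <- matrix(character(0), ncol = 2L)
    if (length(fields)) {
        widths <- lengths(fields)
        if (!all(widths %in% c(2L, 3L)) || length(unique(widths)) != 1L) {
            bad <- lineNo[which(!(widths %in% c(2L, 3L)) |
                                widths != widths[1L])[1L]]
            stop(sprintf("malformed network line %d (need 2 or 3 tab-separated fields)",
                         bad), call. = FALSE)
        }
        f <- vapply(fields, `[`, character(1L), 1L)
        t <- vapply(fields, `[`, character(1L), widths[1L])
        if (any(f == t)) {
            bad <- lineNo[which(f == t)[1L]]
            stop(sprintf("self-loop at line %d is not allowed", bad),
                 call. = FALSE)
        }
        edges <- cbind(f, t)
    }
    GeneNetwork(genes = genes, edges = edges)
}
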