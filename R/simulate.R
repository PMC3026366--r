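# Synchronous Boolean-network simulator for generating benchmark time
# courses with known ground-truth structure.

#' Draw a random Boolean network model
#'
#' Each gene draws an in-degree from Binomial(maxInDegree, edgeDensity),
#' its parents uniformly without replacement (excluding itself), a
#' complete random truth table over its parents' joint states, and one
#' regulatory delay per parent, uniform on 1..maxEdgeDelay.  Genes that
#' draw no parents act as exogenous inputs during simulation.  By default
#' truth tables are balanced (half their outputs ON): median-based
#' quantization of real profiles makes every gene roughly half-ON over
#' the time course, so a faithful binary stand-in should keep gene
#' occupancies near 1/2 rather than let biased rules pin genes to one
#' state.  The same seed and parameters always reproduce the same model.
#'
#' @param n number of genes (>= 2).
#' @param maxInDegree largest allowed parent count (default 3).
#' @param edgeDensity per-slot probability of drawing a parent, in [0, 1]
#'   (default 0.5); 0 yields the empty network.
#' @param noise per-step symbol flip probability in [0, 0.5) (default
#'   0.05, a mild microarray-style corruption).
#' @param maxEdgeDelay largest per-edge regulatory delay (default 1, the
#'   conventional unit delay).
#' @param balancedTables if \code{TRUE} (default), each truth table is a
#'   random permutation of half 0s and half 1s; if \code{FALSE}, entries
#'   are i.i.d. uniform.
#' @param seed optional integer seed.
#' @return a \code{\link{BooleanNetworkModel}}.
#' @export
randomBooleanNetwork <- function(n, maxInDegree = 3L, edgeDensity = 0.5,
                                 noise = 0.05, maxEdgeDelay = 1L,
                                 balancedTables = TRUE, seed = NULL) {
    n <- as.integer(n)
    maxInDegree <- as.integer(maxInDegree)
    if (n < 2L || maxInDegree < 1L || maxInDegree > n - 1L)
        stop("need n >= 2 and 1 <= maxInDegree <= n - 1", call. = FALSE)
    if (edgeDensity < 0 || edgeDensity > 1)
        stop("'edgeDensity' must lie in [0, 1]", call. = FALSE)
    if (!is.null(seed))
        set.seed(as.integer(seed))
    ids <- sprintf("G%d", seq_len(n))
    parents <- tables <- delays <- vector("list", n)
    for (j in seq_len(n)) {
        k <- stats::rbinom(1L, maxInDegree, edgeDensity)
        pj <- if (k) sample(setdiff(seq_len(n), j), k) else integer(0)
        parents[[j]] <- as.integer(pj)
        tables[[j]] <- if (balancedTables && k >= 1L)
            sample(rep(c(0L, 1L), 2L^(k - 1L)))
        else sample(c(0L, 1L), 2L^k, replace = TRUE)
        delays[[j]] <- if (k) sample.int(as.integer(maxEdgeDelay), k,
                                         replace = TRUE) else integer(0)
    }
    new("BooleanNetworkModel", genes = ids, parents = parents,
        tables = tables, delays = delays, noise = noise)
}

#' True regulatory network of a Boolean model
#'
#' @param model a \code{\link{BooleanNetworkModel}}.
#' @return the \code{\link{GeneNetwork}} of parent -> gene edges.
#' @export
trueNetwork <- function(model) {
    stopifnot(is(model, "BooleanNetworkModel"))
    ids <- model@genes
    e <- do.call(rbind, lapply(seq_along(ids), function(j) {
        pj <- model@parents[[j]]
        if (length(pj)) cbind(ids[pj], ids[j]) else NULL
    }))
    GeneNetwork(genes = ids, edges = e)
}

#' Simulate a binary time course from a Boolean model
#'
#' Starting from a uniformly random initial state, genes update
#' synchronously: gene j at time t takes its truth-table output on its
#' parents' states at t - delay (clamped to the first time point during
#' the initial transient), after which the symbol is flipped with the
#' model's noise probability.  Parentless genes act as exogenous inputs:
#' they follow a slow two-state Markov chain that switches with
#' probability \code{inputSwitch} per step, mimicking the strongly
#' autocorrelated trajectories that kinetic in-silico generators produce
#' (an i.i.d. input would make the drive uncorrelated between consecutive
#' samples, which quantized kinetic data never is).  With noise 0 and all
#' delays 1 the regulated genes follow exactly the deterministic
#' synchronous Boolean dynamics of the model.
#'
#' @param model a \code{\link{BooleanNetworkModel}}.
#' @param m number of time points (>= 2).
#' @param seed optional integer seed.
#' @param inputSwitch per-step state-switch probability of exogenous
#'   (parentless) genes, in (0, 1] (default 0.15, a dwell time of about 7
#'   sampling intervals).
#' @return a \code{\link{BinaryExpressionSeries}} (n x m).
#' @export
simulateSeries <- function(model, m, seed = NULL, inputSwitch = 0.15) {
    stopifnot(is(model, "BooleanNetworkModel"))
    m <- as.integer(m)
    if (m < 2L)
        stop("need at least 2 time points", call. = FALSE)
    if (!is.null(seed))
        set.seed(as.integer(seed))
    n <- length(model@genes)
    x <- matrix(0L, n, m, dimnames = list(model@genes, NULL))
    x[, 1L] <- sample(c(0L, 1L), n, replace = TRUE)
    for (t in 2:m) {
        for (j in seq_len(n)) {
            pj <- model@parents[[j]]
            if (length(pj) == 0L) {
                sw <- stats::runif(1L) < inputSwitch
                x[j, t] <- if (sw) 1L - x[j, t - 1L] else x[j, t - 1L]
                next
            }
            src <- pmax(t - model@delays[[j]], 1L)
            bits <- x[cbind(pj, src)]
            x[j, t] <- model@tables[[j]][1L + sum(bits * 2L^(seq_along(pj) - 1L))]
        }
        if (model@noise > 0) {
            flip <- stats::runif(n) < model@noise
            x[flip, t] <- 1L - x[flip, t]
        }
    }
    BinaryExpressionSeries(x)
}

#' Generate a network and long time course for saturation studies
#'
#' Convenience wrapper producing one random Boolean network and one
#' mMax-point simulated series from it, intended for prefix sweeps
#' (first 15 points, then 20, ...).  A prefix of the returned matrix is
#' exactly its first columns, so sweep results at smaller sizes coincide
#' with standalone runs on truncated data.
#'
#' @param n number of genes.
#' @param mMax total number of time points (>= 15, so that at least one
#'   standard sweep prefix exists).
#' @param seed integer seed (drives both the network and the series).
#' @param ... further arguments passed to
#'   \code{\link{randomBooleanNetwork}} (noise, density, delays ...).
#' @return list with elements \code{model} (the
#'   \code{BooleanNetworkModel}), \code{series} (the
#'   \code{BinaryExpressionSeries}) and \code{network} (the true
#'   \code{GeneNetwork}).
#' @export
saturationDataset <- function(n, mMax, seed = NULL, ...) {
    mMax <- as.integer(mMax)
    if (mMax < 15L)
        stop("'mMax' must be at least 15", call. = FALSE)
    model <- randomBooleanNetwork(n, seed = seed, ...)
    series <- simulateSeries(model, mMax)
    list(model = model, series = series, network = trueNetwork(model))
}
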