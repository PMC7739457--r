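#' Simulation parameters for Gamma-Poisson single-cell counts
#'
#' An S4 class specifying the generative model: gene base means are Gamma
#' distributed; cell-type (group) identity multiplies a random subset of
#' genes by log-normal differential-expression factors (inverted with
#' probability 1/2 for down-regulation); batches multiply every gene by a
#' log-normal batch factor; per-cell expected counts are scaled so each
#' cell's total equals its log-normal library size; observed counts are
#' Poisson draws, optionally thinned by a logistic-in-log-mean dropout.
#'
#' @slot nCells,nGenes,nGroups,nBatches Problem dimensions.
#' @slot groupProportions Simplex vector of group proportions.
#' @slot deProb Probability a gene is differentially expressed per group.
#' @slot deFacLoc,deFacScale Log-normal parameters of DE factors.
#' @slot meanShape,meanRate Gamma parameters of gene base means.
#' @slot libLoc,libScale Log-normal library-size parameters.
#' @slot batchFacLoc,batchFacScale Log-normal batch-factor parameters.
#' @slot dropoutEnabled Apply logistic dropout after Poisson sampling.
#' @slot dropoutMid Logistic midpoint on the log-mean scale.
#' @slot dropoutShape Logistic shape (typically negative, so high-mean
#'   entries drop out less).
#' @slot seed Integer seed; fixed seeds reproduce the dataset bit-exactly.
#'
#' @seealso [SimParams()], [simulateCounts()]
#' @exportClass SimParams
setClass("SimParams",
    representation(
        nCells = "integer", nGenes = "integer", nGroups = "integer",
        groupProportions = "numeric",
        deProb = "numeric", deFacLoc = "numeric", deFacScale = "numeric",
        meanShape = "numeric", meanRate = "numeric",
        libLoc = "numeric", libScale = "numeric",
        nBatches = "integer",
        batchFacLoc = "numeric", batchFacScale = "numeric",
        dropoutEnabled = "logical", dropoutMid = "numeric",
        dropoutShape = "numeric",
        seed = "integer"
    )
)

setValidity("SimParams", function(object) {
    msg <- character(0)
    if (object@nCells < 1L || object@nGenes < 1L)
        msg <- c(msg, "nCells and nGenes must be positive")
    if (object@nGroups < 1L || object@nBatches < 1L)
        msg <- c(msg, "nGroups and nBatches must be positive")
    if (length(object@groupProportions) != object@nGroups ||
        any(object@groupProportions <= 0) ||
        abs(sum(object@groupProportions) - 1) > 1e-8)
        msg <- c(msg, "groupProportions must be a positive simplex of length nGroups")
    if (object@deProb < 0 || object@deProb > 1)
        msg <- c(msg, "deProb must lie in [0, 1]")
    if (object@meanShape <= 0 || object@meanRate <= 0)
        msg <- c(msg, "Gamma mean parameters must be positive")
    if (object@deFacScale < 0 || object@libScale < 0 ||
        object@batchFacScale < 0)
        msg <- c(msg, "log-normal scale parameters must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' Defaults follow splatter's standard parameterization (Gamma mean shape
#' 0.6 / rate 0.3, library log-mean 11 / log-sd 0.2, 10% DE genes with
#' log-normal(0.1, 0.4) factors, batch factors log-normal(0.1, 0.1)), with
#' the benchmark design's 2000 cells x 10,000 genes x 5 equal cell types.
#'
#' @param nCells,nGenes,nGroups,nBatches Problem dimensions.
#' @param groupProportions Group proportions (default equal).
#' @param deProb,deFacLoc,deFacScale Differential-expression knobs.
#' @param meanShape,meanRate Gamma parameters of gene base means.
#' @param libLoc,libScale Library-size log-normal parameters.
#' @param batchFacLoc,batchFacScale Batch-factor log-normal parameters.
#' @param dropout Apply logistic dropout.
#' @param dropoutMid,dropoutShape Logistic dropout parameters.
#' @param seed Integer seed.
#' @return A [SimParams-class] object.
#' @export
SimParams <- function(nCells = 2000, nGenes = 10000, nGroups = 5,
                      groupProportions = rep(1 / nGroups, nGroups),
                      deProb = 0.1, deFacLoc = 0.1, deFacScale = 0.4,
                      meanShape = 0.6, meanRate = 0.3,
                      libLoc = 11, libScale = 0.2,
                      nBatches = 1, batchFacLoc = 0.1, batchFacScale = 0.1,
                      dropout = FALSE, dropoutMid = 0, dropoutShape = -1,
                      seed = 1) {
    new("SimParams",
        nCells = as.integer(nCells), nGenes = as.integer(nGenes),
        nGroups = as.integer(nGroups),
        groupProportions = as.numeric(groupProportions),
        deProb = deProb, deFacLoc = deFacLoc, deFacScale = deFacScale,
        meanShape = meanShape, meanRate = meanRate,
        libLoc = libLoc, libScale = libScale,
        nBatches = as.integer(nBatches),
        batchFacLoc = batchFacLoc, batchFacScale = batchFacScale,
        dropoutEnabled = as.logical(dropout),
        dropoutMid = dropoutMid, dropoutShape = dropoutShape,
        seed = as.integer(seed))
}

# Exact group sizes from proportions (largest-remainder rounding).
.groupSizes <- function(n, prop) {
    sizes <- diff(c(0L, round(cumsum(prop) * n)))
    sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
    as.integer(sizes)
}

#' Simulate a single-cell count matrix
#'
#' Draws a labeled genes x cells count matrix under the Gamma-Poisson model
#' described in [SimParams-class]. Cells are assigned to groups at the
#' configured proportions (random order) and to batches in contiguous
#' blocks (the first `nCells / nBatches` cells form batch 1, and so on).
#' Expected counts are normalized per cell so the expected total equals the
#' cell's library size.
#'
#' @param params A [SimParams-class].
#' @return A `SingleCellExperiment` with assays `counts` (observed),
#'   `trueCounts` (pre-dropout), `cellMeans` (Poisson means) and, when
#'   dropout is enabled, `dropoutMask` (1 where a positive true count was
#'   zeroed); `colData` columns `group`, `batch`, `libSize`; the parameters
#'   in `metadata(x)$simParams`.
#' @examples
#' sce <- simulateCounts(SimParams(nCells = 50, nGenes = 100, seed = 1))
#' table(sce$group)
#' @export
simulateCounts <- function(params) {
    stopifnot(methods::is(params, "SimParams"))
    methods::validObject(params)
    G <- params@nGenes
    n <- params@nCells
    sim <- .withSeed(params@seed, {
        baseMeans <- stats::rgamma(G, shape = params@meanShape,
                                   rate = params@meanRate)
        groupNames <- paste0("Group", seq_len(params@nGroups))
        groups <- sample(rep(groupNames, .groupSizes(n,
                                                     params@groupProportions)))
        batchNames <- paste0("Batch", seq_len(params@nBatches))
        batches <- rep(batchNames, .groupSizes(n, rep(1 / params@nBatches,
                                                      params@nBatches)))
        # DE factors per group x gene; inverted with prob 1/2
        deFac <- matrix(1, nrow = G, ncol = params@nGroups,
                        dimnames = list(NULL, groupNames))
        for (g in seq_len(params@nGroups)) {
            isDE <- stats::runif(G) < params@deProb
            fac <- exp(stats::rnorm(G, params@deFacLoc, params@deFacScale))
            down <- stats::runif(G) < 0.5
            fac[down] <- 1 / fac[down]
            deFac[isDE, g] <- fac[isDE]
        }
        # batch factors per batch x gene
        batchFac <- matrix(1, nrow = G, ncol = params@nBatches,
                           dimnames = list(NULL, batchNames))
        if (params@nBatches > 1L) {
            for (b in seq_len(params@nBatches))
                batchFac[, b] <- exp(stats::rnorm(G, params@batchFacLoc,
                                                  params@batchFacScale))
        }
        libSize <- exp(stats::rnorm(n, params@libLoc, params@libScale))
        # per-cell means, normalized to the library size
        lambda <- matrix(0, nrow = G, ncol = n)
        for (c in seq_len(n)) {
            mgc <- baseMeans * deFac[, groups[c]] * batchFac[, batches[c]]
            lambda[, c] <- libSize[c] * mgc / sum(mgc)
        }
        counts <- matrix(stats::rpois(G * n, lambda), nrow = G, ncol = n)
        list(counts = counts, lambda = lambda, groups = groups,
             batches = batches, libSize = libSize)
    })
    geneIds <- sprintf("Gene%05d", seq_len(G))
    cellIds <- sprintf("Cell%05d", seq_len(n))
    dimnames(sim$counts) <- list(geneIds, cellIds)
    dimnames(sim$lambda) <- list(geneIds, cellIds)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = sim$counts, trueCounts = sim$counts,
                      cellMeans = sim$lambda),
        colData = S4Vectors::DataFrame(group = sim$groups,
                                       batch = sim$batches,
                                       libSize = sim$libSize,
                                       row.names = cellIds))
    S4Vectors::metadata(sce)$simParams <- params
    if (params@dropoutEnabled)
        sce <- applyDropout(sce, mid = params@dropoutMid,
                            shape = params@dropoutShape,
                            seed = params@seed + 1L)
    sce
}

#' Apply logistic dropout to a simulated dataset
#'
#' Each entry is zeroed independently with probability
#' \deqn{p_{gc} = \frac{1}{1 + \exp(-s\,(\ln(\mu_{gc} + \epsilon) - x_0))}}
#' where \eqn{\mu_{gc}} is the pre-Poisson expected count, \eqn{x_0} the
#' midpoint `mid` and \eqn{s} the `shape` (negative values make high-mean
#' entries safer). The mask records which originally positive true counts
#' were zeroed. Dropout always starts from `trueCounts`, so re-applying
#' with new parameters replaces, rather than compounds, a previous mask.
#'
#' @param data A `SingleCellExperiment` from [simulateCounts()].
#' @param mid Logistic midpoint \eqn{x_0} on the log-mean scale.
#' @param shape Logistic shape \eqn{s}.
#' @param seed Integer seed for the Bernoulli draws.
#' @param eps Guard added to the mean before taking logs (default 1e-8).
#' @return The dataset with updated `counts` and a `dropoutMask` assay.
#' @export
applyDropout <- function(data, mid, shape, seed, eps = 1e-8) {
    an <- SummarizedExperiment::assayNames(data)
    if (!all(c("trueCounts", "cellMeans") %in% an))
        stop("dataset lacks trueCounts/cellMeans assays; ",
             "generate it with simulateCounts()", call. = FALSE)
    true <- SummarizedExperiment::assay(data, "trueCounts")
    lambda <- SummarizedExperiment::assay(data, "cellMeans")
    p <- 1 / (1 + exp(-shape * (log(lambda + eps) - mid)))
    drop <- .withSeed(seed, matrix(stats::runif(length(p)) < p,
                                   nrow = nrow(p)))
    counts <- true
    counts[drop] <- 0L
    mask <- matrix(0L, nrow = nrow(true), ncol = ncol(true),
                   dimnames = dimnames(true))
    mask[drop & true > 0L] <- 1L
    SummarizedExperiment::assay(data, "counts") <- counts
    SummarizedExperiment::assay(data, "dropoutMask") <- mask
    S4Vectors::metadata(data)$dropout <-
        list(mid = mid, shape = shape, seed = as.integer(seed), eps = eps)
    data
}

#' Measured dropout rate
#'
#' Fraction of originally non-zero entries of the true counts that were
#' zeroed by dropout.
#'
#' @param data A dataset with a `dropoutMask` assay.
#' @return A fraction in \eqn{[0, 1]}.
#' @export
dropoutRate <- function(data) {
    an <- SummarizedExperiment::assayNames(data)
    if (!"dropoutMask" %in% an)
        stop("dataset has no dropoutMask assay; apply dropout first",
             call. = FALSE)
    true <- SummarizedExperiment::assay(data, "trueCounts")
    mask <- SummarizedExperiment::assay(data, "dropoutMask")
    npos <- sum(true > 0L)
    if (npos == 0L) return(0)
    sum(mask) / npos
}

#' Fraction of zero entries in a count matrix
#'
#' @param counts A matrix (or `SummarizedExperiment`, whose `counts` assay
#'   is used).
#' @return Fraction of entries equal to zero.
#' @export
zeroFraction <- function(counts) {
    if (methods::is(counts, "SummarizedExperiment"))
        counts <- SummarizedExperiment::assay(counts, "counts")
    if (length(counts) == 0L)
        stop("empty matrix", call. = FALSE)
    mean(counts == 0)
}

# Solve for the logistic midpoint whose *expected* measured dropout rate
# (weighted by the probability an entry is non-zero before dropout) hits
# `target`. Monotone in mid for shape < 0 is handled by uniroot on the
# signed difference; entries are subsampled deterministically for speed.
.dropoutMidForRate <- function(lambda, shape, target, eps = 1e-8,
                               maxEntries = 200000L) {
    v <- as.vector(lambda)
    if (length(v) > maxEntries)
        v <- v[seq(1L, length(v), length.out = maxEntries)]
    w <- 1 - exp(-v)               # P(true count > 0)
    lv <- log(v + eps)
    f <- function(mid) {
        p <- 1 / (1 + exp(-shape * (lv - mid)))
        sum(w * p) / sum(w) - target
    }
    lo <- min(lv) - 50
    hi <- max(lv) + 50
    stats::uniroot(f, lower = min(lo, hi), upper = max(lo, hi),
                   tol = 1e-10)$root
}

#' Build the benchmark simulation suites
#'
#' Three designs: `SIM_I` is one batch of 5 equal cell types with no
#' dropout (cell-type identification); `SIM_II` is the same design split
#' into two equal batches with multiplicative batch effects (cross-batch
#' mapping); `SIM_III` is six datasets sharing one base count matrix, with
#' logistic dropout applied at midpoints solved so the measured dropout
#' rates step through approximately 0, 15.4, 25.2, 35.3, 43.4 and 53.6
#' percent of originally non-zero entries.
#'
#' @param which `"SIM_I"`, `"SIM_II"` or `"SIM_III"`.
#' @param seed Integer seed.
#' @param nCells,nGenes Dimensions (defaults: the benchmark design's 2000
#'   cells x 10,000 genes; pass smaller values for quick experiments).
#' @param ... Further arguments passed to [SimParams()].
#' @return For `SIM_I`/`SIM_II`, a single `SingleCellExperiment`; for
#'   `SIM_III`, a named list of six (`SIM_III-0` ... `SIM_III-5`) in order
#'   of increasing dropout.
#' @export
makeSimSuite <- function(which = c("SIM_I", "SIM_II", "SIM_III"), seed = 1,
                         nCells = 2000, nGenes = 10000, ...) {
    which <- match.arg(which)
    seed <- as.integer(seed)
    if (which == "SIM_I")
        return(simulateCounts(SimParams(nCells = nCells, nGenes = nGenes,
                                        nGroups = 5, nBatches = 1,
                                        seed = seed, ...)))
    if (which == "SIM_II")
        return(simulateCounts(SimParams(nCells = nCells, nGenes = nGenes,
                                        nGroups = 5, nBatches = 2,
                                        seed = seed, ...)))
    base <- simulateCounts(SimParams(nCells = nCells, nGenes = nGenes,
                                     nGroups = 5, nBatches = 1,
                                     seed = seed, ...))
    targets <- c(0.1544, 0.2515, 0.3528, 0.4341, 0.5360)
    lambda <- SummarizedExperiment::assay(base, "cellMeans")
    out <- vector("list", 6L)
    # level 0: no dropout, explicit zero mask so dropoutRate() is defined
    zero <- base
    mask <- matrix(0L, nrow = nrow(zero), ncol = ncol(zero),
                   dimnames = dimnames(SummarizedExperiment::assay(zero)))
    SummarizedExperiment::assay(zero, "dropoutMask") <- mask
    out[[1L]] <- zero
    for (t in seq_along(targets)) {
        mid <- .dropoutMidForRate(lambda, shape = -1, target = targets[t])
        out[[t + 1L]] <- applyDropout(base, mid = mid, shape = -1,
                                      seed = seed + t)
    }
    names(out) <- paste0("SIM_III-", 0:5)
    out
}
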