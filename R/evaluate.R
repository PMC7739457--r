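#' Confusion matrix of true versus predicted labels
#'
#' @param true,predicted Equal-length label vectors.
#' @return An integer C x C matrix, rows = true class, columns = predicted
#'   class, with the sorted union of observed labels as dimnames. Classes
#'   absent from one vector contribute zero rows/columns.
#' @examples
#' confusionMatrix(c("a", "a", "b"), c("a", "a", "b"))
#' @export
confusionMatrix <- function(true, predicted) {
    if (length(true) != length(predicted))
        stop("true and predicted labels differ in length", call. = FALSE)
    if (length(true) < 1L)
        stop("at least one label pair required", call. = FALSE)
    lev <- sort(unique(c(as.character(true), as.character(predicted))))
    M <- table(factor(true, levels = lev), factor(predicted, levels = lev))
    M <- unclass(M)
    names(dimnames(M)) <- NULL
    storage.mode(M) <- "integer"
    M
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement
#' \deqn{\kappa = \frac{P_0 - P_e}{1 - P_e}}
#' with observed agreement \eqn{P_0 = \sum_i M_{ii} / \sum_{ij} M_{ij}} and
#' chance agreement
#' \eqn{P_e = \sum_a (\mathrm{row}_a \cdot \mathrm{col}_a) / (\sum_{ij} M_{ij})^2}.
#' Returns 1 for perfect diagonal agreement and 0 when observed agreement
#' equals chance. In the degenerate case \eqn{P_e = 1} (a single class),
#' returns 1 when \eqn{P_0 = 1} and signals an error otherwise.
#'
#' @param M A square non-negative confusion matrix (true classes in rows).
#' @return Kappa in \eqn{[-1, 1]}.
#' @examples
#' cohensKappa(matrix(c(4, 2, 1, 3), 2))  # 0.4
#' @export
cohensKappa <- function(M) {
    if (!is.matrix(M) || nrow(M) != ncol(M))
        stop("M must be a square confusion matrix", call. = FALSE)
    if (any(M < 0))
        stop("confusion matrix entries must be non-negative", call. = FALSE)
    total <- sum(M)
    if (total <= 0)
        stop("confusion matrix is empty", call. = FALSE)
    p0 <- sum(diag(M)) / total
    pe <- sum(rowSums(M) * colSums(M)) / total^2
    if (abs(1 - pe) < .Machine$double.eps * 4) {
        if (abs(1 - p0) < .Machine$double.eps * 4) return(1)
        stop("kappa undefined: chance agreement is 1 but observed is not",
             call. = FALSE)
    }
    (p0 - pe) / (1 - pe)
}

# Seeded partition of n cells into nFolds disjoint folds of near-equal size.
.makeFolds <- function(n, nFolds, seed) {
    if (nFolds < 2L || nFolds > n)
        stop("need 2 <= nFolds <= number of cells (", n, ")", call. = FALSE)
    perm <- .withSeed(seed, sample.int(n))
    unname(split(perm, cut(seq_len(n), nFolds, labels = FALSE)))
}

#' Cell-mapping cross-validation with Cohen's kappa
#'
#' Splits the cells into `nFolds` disjoint random folds (each about
#' 100/nFolds percent of the dataset). For each fold, the remaining cells
#' form the reference, the fold members are mapped to their nearest
#' reference neighbor by the two-stage multi-probe search, and Cohen's
#' kappa between mapped and true cell types is recorded. The mean of the
#' fold scores is the CV result. Cells are encoded once with the
#' configuration's seeded structures (folds share them, exactly as separate
#' [buildIndex()] calls would).
#'
#' @param data A labeled `SingleCellExperiment` (colData column `group`) or
#'   a genes x cells matrix plus `labels`.
#' @param config A [HashConfig-class].
#' @param nFolds Number of folds (default 5, i.e. 20% query folds).
#' @param seed Integer seed for the fold split.
#' @param labels Optional per-cell labels overriding `colData$group`.
#' @param initialRadius Starting multi-probe radius.
#' @param tag Experiment tag stored in the result.
#' @return A [CVResult-class].
#' @export
crossValidate <- function(data, config, nFolds = 5, seed = 1,
                          labels = NULL, initialRadius = 2L,
                          tag = "selfmap") {
    labels <- .resolveLabels(data, labels)
    if (is.null(labels))
        stop("dataset has no cell-type labels", call. = FALSE)
    x <- .asExpressionMatrix(data)
    n <- ncol(x)
    if (length(labels) != n)
        stop("labels length does not match cell count", call. = FALSE)
    folds <- .makeFolds(n, as.integer(nFolds), seed)
    enc <- encodeCells(x, config)
    scores <- vapply(folds, function(fold) {
        ref <- setdiff(seq_len(n), fold)
        res <- .searchEncoded(enc$long[ref, , drop = FALSE],
                              enc$short[ref, , drop = FALSE],
                              enc$long[fold, , drop = FALSE],
                              enc$short[fold, , drop = FALSE],
                              initialRadius = as.integer(initialRadius))
        predicted <- labels[ref][res$nearest]
        cohensKappa(confusionMatrix(labels[fold], predicted))
    }, numeric(1))
    methods::new("CVResult", foldScores = unname(scores), config = config,
                 tag = tag)
}

# Shared harness configuration: hash length k with m fixed (20 by default),
# SimHash at k bits, mirroring the benchmark design where only the fly
# schemes get the m-fold embedding.
.harnessConfig <- function(method, m, k, alpha, seed) {
    HashConfig(method, m = m, k = k, alpha = alpha, seed = seed,
               simhashBits = "k")
}

#' Self-mapping experiment over methods and hash lengths
#'
#' Runs [crossValidate()] for each combination of hashing method and hash
#' length `k` (with `m` and `alpha` fixed) and returns the per-fold kappa
#' scores in long format. SimHash is run at `k` bits while the fly schemes
#' use the `m * k`-bit embedding, matching the benchmark design.
#'
#' @param data A labeled dataset (see [crossValidate()]).
#' @param methods Methods to compare.
#' @param kValues Hash lengths to sweep.
#' @param m Number of shuffle groups (default 20).
#' @param alpha Sampling rate (default 0.1).
#' @param nFolds,seed Cross-validation settings; `seed` seeds both the
#'   encoder structures and the fold split.
#' @return A data.frame with columns `method`, `m`, `k`, `alpha`, `fold`,
#'   `kappa`.
#' @seealso [summarizeScores()]
#' @export
runSelfmapExperiment <- function(data,
                                 methods = c("densefly", "flyhash",
                                             "simhash"),
                                 kValues = c(64, 128, 256, 512, 1024),
                                 m = 20, alpha = 0.1, nFolds = 5, seed = 1) {
    out <- list()
    for (method in methods) {
        for (k in kValues) {
            cfg <- .harnessConfig(method, m, k, alpha, seed)
            cv <- crossValidate(data, cfg, nFolds = nFolds, seed = seed)
            out[[length(out) + 1L]] <- data.frame(
                method = method, m = m, k = k, alpha = alpha,
                fold = seq_along(foldScores(cv)), kappa = foldScores(cv))
        }
    }
    do.call(rbind, out)
}

#' Cross-batch mapping experiment
#'
#' Queries are drawn as `nFolds` disjoint folds from the source batch; the
#' reference is the entire target batch. Each fold's queries are mapped to
#' their nearest target-batch neighbor and scored with Cohen's kappa.
#'
#' @param data A labeled two-batch dataset (colData columns `group` and
#'   `batch`).
#' @param config A [HashConfig-class].
#' @param direction `"1to2"` (batch 1 queries against batch 2) or `"2to1"`.
#' @param nFolds,seed Cross-validation settings.
#' @param initialRadius Starting multi-probe radius.
#' @return A [CVResult-class] tagged with the direction.
#' @export
runBatchExperiment <- function(data, config, direction = c("1to2", "2to1"),
                               nFolds = 5, seed = 1, initialRadius = 2L) {
    direction <- match.arg(direction)
    cd <- SummarizedExperiment::colData(data)
    if (!all(c("group", "batch") %in% colnames(cd)))
        stop("dataset must carry 'group' and 'batch' annotations",
             call. = FALSE)
    batches <- sort(unique(as.character(cd$batch)))
    if (length(batches) != 2L)
        stop("batch experiment requires exactly 2 batches, found ",
             length(batches), call. = FALSE)
    src <- if (direction == "1to2") batches[1L] else batches[2L]
    tgt <- setdiff(batches, src)
    labels <- as.character(cd$group)
    x <- .asExpressionMatrix(data)
    srcIdx <- which(cd$batch == src)
    tgtIdx <- which(cd$batch == tgt)
    enc <- encodeCells(x, config)
    folds <- .makeFolds(length(srcIdx), as.integer(nFolds), seed)
    scores <- vapply(folds, function(fold) {
        q <- srcIdx[fold]
        res <- .searchEncoded(enc$long[tgtIdx, , drop = FALSE],
                              enc$short[tgtIdx, , drop = FALSE],
                              enc$long[q, , drop = FALSE],
                              enc$short[q, , drop = FALSE],
                              initialRadius = as.integer(initialRadius))
        predicted <- labels[tgtIdx][res$nearest]
        cohensKappa(confusionMatrix(labels[q], predicted))
    }, numeric(1))
    methods::new("CVResult", foldScores = unname(scores), config = config,
                 tag = paste0("batch:", direction))
}

#' Dropout-sweep experiment
#'
#' Runs the self-mapping cross-validation on each dataset of a dropout
#' suite (see [makeSimSuite()] `"SIM_III"`), for each method and hash
#' length, recording the measured dropout rate of each dataset.
#'
#' @param suite A list of datasets with `dropoutMask` assays, in increasing
#'   dropout order.
#' @param methods,kValues,m,alpha,nFolds,seed As in
#'   [runSelfmapExperiment()].
#' @return A data.frame with columns `level`, `dropout_rate`, `method`,
#'   `m`, `k`, `alpha`, `fold`, `kappa`.
#' @export
runDropoutExperiment <- function(suite,
                                 methods = c("densefly", "flyhash",
                                             "simhash"),
                                 kValues = c(32, 64, 128, 256),
                                 m = 20, alpha = 0.1, nFolds = 5, seed = 1) {
    out <- list()
    for (lvl in seq_along(suite)) {
        data <- suite[[lvl]]
        rate <- dropoutRate(data)
        for (method in methods) {
            for (k in kValues) {
                cfg <- .harnessConfig(method, m, k, alpha, seed)
                cv <- crossValidate(data, cfg, nFolds = nFolds, seed = seed)
                out[[length(out) + 1L]] <- data.frame(
                    level = lvl - 1L, dropout_rate = rate, method = method,
                    m = m, k = k, alpha = alpha,
                    fold = seq_along(foldScores(cv)),
                    kappa = foldScores(cv))
            }
        }
    }
    do.call(rbind, out)
}

#' Summarize fold-level scores
#'
#' Mean kappa per condition (all columns except `fold` and `kappa`).
#'
#' @param scores A fold-level data.frame from one of the experiment
#'   harnesses.
#' @return A data.frame with one row per condition and a `mean_kappa`
#'   column.
#' @export
summarizeScores <- function(scores) {
    keys <- setdiff(colnames(scores), c("fold", "kappa"))
    agg <- stats::aggregate(scores$kappa, by = scores[keys], FUN = mean)
    names(agg)[ncol(agg)] <- "mean_kappa"
    agg
}
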