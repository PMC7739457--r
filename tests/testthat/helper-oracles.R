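# Independent brute-force oracles (explicit loops, no shared code with the
# package's matrix-algebra paths) and small fixture builders.

oracleHamming <- function(a, b) {
    n <- 0L
    for (i in seq_along(a)) if (a[i] != b[i]) n <- n + 1L
    n
}

# Two-stage exhaustive search: filter references by short-hash distance
# under the escalating radius, then argmin long-hash distance, ties broken
# by lowest reference index.
oracleSearch <- function(refLong, refShort, qLong, qShort, initialRadius) {
    nRef <- nrow(refShort)
    M <- ncol(refShort)
    shortD <- integer(nRef)
    for (i in seq_len(nRef)) shortD[i] <- oracleHamming(refShort[i, ], qShort)
    r <- initialRadius
    repeat {
        if (r >= M) {
            cand <- seq_len(nRef)
            r <- M
            break
        }
        cand <- which(shortD <= r)
        if (length(cand) > 0) break
        r <- if (r == 0) 1 else 2 * r
    }
    best <- NA_integer_
    bestD <- Inf
    for (i in cand) {
        d <- oracleHamming(refLong[i, ], qLong)
        if (d < bestD) {
            bestD <- d
            best <- i
        }
    }
    list(nearest = best, long_distance = bestD, radius_used = r,
         candidate_count = length(cand))
}

# Cohen's kappa straight from its definition, all sums as loops.
oracleKappa <- function(M) {
    C <- nrow(M)
    total <- 0
    diag_ <- 0
    for (i in seq_len(C)) for (j in seq_len(C)) total <- total + M[i, j]
    for (i in seq_len(C)) diag_ <- diag_ + M[i, i]
    p0 <- diag_ / total
    pe <- 0
    for (a in seq_len(C)) {
        rowa <- 0
        cola <- 0
        for (j in seq_len(C)) {
            rowa <- rowa + M[a, j]
            cola <- cola + M[j, a]
        }
        pe <- pe + rowa * cola
    }
    pe <- pe / total^2
    (p0 - pe) / (1 - pe)
}

oracleConfusion <- function(true, pred) {
    lev <- sort(unique(c(true, pred)))
    M <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
    for (i in seq_along(true))
        M[true[i], pred[i]] <- M[true[i], pred[i]] + 1L
    M
}

# Exact 1-nearest-neighbor classifier in expression space (Euclidean,
# explicit loops over a small reference).
oracleNNClassify <- function(refX, refLabels, qX) {
    out <- character(ncol(qX))
    for (q in seq_len(ncol(qX))) {
        bestD <- Inf
        for (r in seq_len(ncol(refX))) {
            d <- sum((refX[, r] - qX[, q])^2)
            if (d < bestD) {
                bestD <- d
                out[q] <- refLabels[r]
            }
        }
    }
    out
}

# A shuffle-group partition over activations 1..(m*k), groups in order --
# used to feed the printed worked examples to the encoders directly.
fixedGroups <- function(m, k) {
    g <- unname(split(seq_len(m * k), rep(seq_len(m), each = k)))
    attr(g, "m") <- as.integer(m)
    attr(g, "k") <- as.integer(k)
    attr(g, "seed") <- 0L
    g
}

# Widely separated cell types: every cell of a type shares one exact
# profile, so any reference split contains same-label twins of each query.
makeTwinDataset <- function(nTypes = 5, perType = 40, nGenes = 100,
                            seed = 42) {
    withr::with_seed(seed, {
        protos <- matrix(stats::rpois(nGenes * nTypes, 5) +
                             1000 * diag(nTypes)[rep(seq_len(nTypes),
                                                     length.out = nGenes), ],
                         nrow = nGenes)
        x <- protos[, rep(seq_len(nTypes), each = perType)]
        colnames(x) <- sprintf("c%03d", seq_len(ncol(x)))
        ord <- sample(ncol(x))
        list(x = x[, ord],
             labels = rep(paste0("T", seq_len(nTypes)),
                          each = perType)[ord])
    })
}

# Small labeled simulated dataset shared by index/evaluate tests.
smallSim <- function(seed = 1, nCells = 120, nGenes = 400) {
    simulateCounts(SimParams(nCells = nCells, nGenes = nGenes, nGroups = 5,
                             seed = seed))
}
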