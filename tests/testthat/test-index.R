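test_that("Hamming distance counts differing positions", {
    expect_identical(hammingDistance(c(0, 1, 0, 1), c(0, 1, 0, 1)), 0L)
    expect_identical(hammingDistance(rep(0, 5), rep(1, 5)), 5L)
    withr::with_seed(3, {
        a <- sample(0:1, 1280, replace = TRUE)
        b <- sample(0:1, 1280, replace = TRUE)
        expect_identical(as.integer(hammingDistance(a, b)),
                         oracleHamming(a, b))
        expect_identical(hammingDistance(a, b), hammingDistance(b, a))
    })
    expect_error(hammingDistance(c(0, 1), c(0, 1, 1)), "length")
})

test_that("buildIndex produces the documented shapes and weights", {
    sce <- smallSim(seed = 2, nCells = 50, nGenes = 200)
    cfg <- HashConfig("flyhash", m = 4, k = 8, alpha = 0.1, seed = 1)
    idx <- buildIndex(sce, cfg)
    expect_s4_class(idx, "HashIndex")
    expect_equal(dim(longHashes(idx)), c(50L, 32L))
    expect_equal(dim(shortHashes(idx)), c(50L, 4L))
    expect_true(all(rowSums(longHashes(idx)) == 4))
    expect_identical(cellLabels(idx),
                     as.character(SummarizedExperiment::colData(sce)$group))
    # determinism
    idx2 <- buildIndex(sce, cfg)
    expect_identical(longHashes(idx), longHashes(idx2))
    expect_identical(shortHashes(idx), shortHashes(idx2))
    expect_error(buildIndex(SummarizedExperiment::assay(sce), cfg,
                            labels = c("a", "b")), "labels length")
})

test_that("querying a reference cell returns it at distance zero", {
    sce <- smallSim(seed = 4, nCells = 60, nGenes = 300)
    x <- SummarizedExperiment::assay(sce)
    for (method in c("densefly", "flyhash", "simhash")) {
        cfg <- HashConfig(method, m = 12, k = 32, alpha = 0.1, seed = 2)
        idx <- buildIndex(sce, cfg)
        res <- multiprobeQuery(idx, x[, 7])
        expect_identical(res$long_distance, 0L)
        # identical vectors hash identically; with a unique hash the cell
        # itself comes back, otherwise the tie rule picks an identical twin
        hit <- match(res$nearest_id, cellIds(idx))
        expect_identical(unname(longHashes(idx)[hit, ]),
                         unname(longHashes(idx)[7, ]))
        keys <- apply(longHashes(idx), 1, paste, collapse = "")
        if (sum(keys == keys[7]) == 1L)
            expect_identical(res$nearest_id, colnames(x)[7])
    }
    # single-reference index returns its only cell regardless of radius
    one <- buildIndex(x[, 1, drop = FALSE],
                      HashConfig("densefly", m = 4, k = 4, alpha = 0.1,
                                 seed = 1))
    res <- multiprobeQuery(one, x[, 30])
    expect_identical(res$nearest_id, colnames(x)[1])
    expect_gte(res$candidate_count, 1L)
})

test_that("multi-probe search matches the two-stage brute-force oracle", {
    sce <- smallSim(seed = 5, nCells = 80, nGenes = 250)
    x <- SummarizedExperiment::assay(sce)
    withr::with_seed(9, qIdx <- sample(80, 25))
    for (method in c("densefly", "flyhash", "simhash")) {
        cfg <- HashConfig(method, m = 6, k = 6, alpha = 0.1, seed = 3,
                          simhashBits = "k")
        idx <- buildIndex(sce, cfg)
        enc <- encodeCells(x, cfg)
        for (r0 in c(0L, 2L)) {
            res <- multiprobeQuery(idx, x[, qIdx], initialRadius = r0)
            for (qi in seq_along(qIdx)) {
                o <- oracleSearch(longHashes(idx), shortHashes(idx),
                                  enc$long[qIdx[qi], ],
                                  enc$short[qIdx[qi], ], r0)
                expect_identical(res$nearest_id[qi], cellIds(idx)[o$nearest])
                expect_identical(res$long_distance[qi],
                                 as.integer(o$long_distance))
                expect_identical(res$radius_used[qi],
                                 as.integer(o$radius_used))
                expect_identical(res$candidate_count[qi],
                                 as.integer(o$candidate_count))
            }
        }
    }
})

test_that("search invariants: candidate ball, optimality, escalation cap", {
    sce <- smallSim(seed = 6, nCells = 70, nGenes = 200)
    x <- SummarizedExperiment::assay(sce)
    cfg <- HashConfig("densefly", m = 5, k = 6, alpha = 0.1, seed = 4)
    idx <- buildIndex(sce, cfg)
    enc <- encodeCells(x, cfg, structures = idx@structures)
    res <- multiprobeQuery(idx, x[, 1:30], initialRadius = 0L)
    for (q in 1:30) {
        ref <- match(res$nearest_id[q], cellIds(idx))
        # returned candidate lies inside the final radius ball (or full set)
        sd <- hammingDistance(shortHashes(idx)[ref, ], enc$short[q, ])
        expect_lte(res$radius_used[q], ncol(shortHashes(idx)))
        if (res$candidate_count[q] < nrow(longHashes(idx)))
            expect_lte(sd, res$radius_used[q])
        # long distance is minimal among all candidates in the ball
        shortAll <- apply(shortHashes(idx), 1L, hammingDistance,
                          enc$short[q, ])
        cand <- if (res$candidate_count[q] == nrow(longHashes(idx)))
            seq_len(nrow(longHashes(idx))) else
            which(shortAll <= res$radius_used[q])
        longCand <- apply(longHashes(idx)[cand, , drop = FALSE], 1L,
                          hammingDistance, enc$long[q, ])
        expect_identical(res$long_distance[q], as.integer(min(longCand)))
    }
})

test_that("results are invariant to reference order with distinct hashes", {
    sce <- smallSim(seed = 7, nCells = 60, nGenes = 300)
    x <- SummarizedExperiment::assay(sce)
    cfg <- HashConfig("densefly", m = 12, k = 32, alpha = 0.1, seed = 5)
    idx <- buildIndex(sce, cfg)
    skipDup <- anyDuplicated(apply(longHashes(idx), 1, paste, collapse = ""))
    expect_identical(skipDup, 0L)  # hashes distinct at this width
    withr::with_seed(8, ord <- sample(60))
    idxPerm <- buildIndex(x[, ord], cfg,
                          labels = as.character(sce$group)[ord])
    res <- multiprobeQuery(idx, x[, 1:10])
    resPerm <- multiprobeQuery(idxPerm, x[, 1:10])
    expect_identical(res$nearest_id, resPerm$nearest_id)
    expect_identical(res$long_distance, resPerm$long_distance)
})

test_that("classification returns the nearest neighbor's label", {
    twin <- makeTwinDataset(perType = 10, nGenes = 80)
    cfg <- HashConfig("densefly", m = 8, k = 8, alpha = 0.2, seed = 6)
    idx <- buildIndex(twin$x, cfg, labels = twin$labels)
    pred <- classifyCells(idx, twin$x)
    expect_identical(pred, twin$labels)
    # unlabeled index refuses to classify
    idxNo <- buildIndex(twin$x, cfg)
    expect_error(classifyCells(idxNo, twin$x[, 1]), "labels")
    # one-label index always returns that label
    idxOne <- buildIndex(twin$x[, 1:5], cfg,
                         labels = rep("only", 5))
    expect_identical(unique(classifyCells(idxOne, twin$x)), "only")
})

test_that("index serialization round-trips bit-exactly", {
    sce <- smallSim(seed = 8, nCells = 40, nGenes = 150)
    for (method in c("densefly", "simhash")) {
        cfg <- HashConfig(method, m = 4, k = 8, alpha = 0.15, seed = 7,
                          centralize = method != "simhash")
        idx <- buildIndex(sce, cfg)
        path <- withr::local_tempfile(fileext = ".idx")
        writeHashIndex(idx, path)
        back <- readHashIndex(path)
        expect_identical(longHashes(back), unname(longHashes(idx)))
        expect_identical(shortHashes(back), unname(shortHashes(idx)))
        expect_identical(cellIds(back), cellIds(idx))
        expect_identical(cellLabels(back), cellLabels(idx))
        expect_equal(hashConfig(back), hashConfig(idx))
        # regenerated structures encode queries identically
        x <- SummarizedExperiment::assay(sce)
        expect_identical(multiprobeQuery(back, x[, 1:5]),
                         multiprobeQuery(idx, x[, 1:5]))
    }
    expect_error(readHashIndex(system.file("DESCRIPTION",
                                           package = "scDenseFly")),
                 "not a hash index")
})
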