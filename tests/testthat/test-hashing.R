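test_that("centralization subtracts the per-cell mean and is idempotent", {
    expect_equal(centralizeExpression(c(1, 2, 3)), c(-1, 0, 1))
    expect_equal(centralizeExpression(rep(5, 4)), rep(0, 4))
    withr::with_seed(7, {
        x <- stats::runif(100, 0, 50)
        loopMean <- 0
        for (v in x) loopMean <- loopMean + v
        loopMean <- loopMean / length(x)
        cx <- centralizeExpression(x)
        expect_equal(cx, x - loopMean)
        expect_lt(abs(mean(cx)), 1e-12)
        expect_equal(centralizeExpression(cx), cx)
    })
    # matrix form centralizes each cell (column)
    m <- matrix(c(1, 2, 3, 4, 4, 4), nrow = 3)
    expect_equal(colMeans(centralizeExpression(m)), c(0, 0))
    expect_error(centralizeExpression(numeric(0)), "at least one gene")
})

test_that("SimHash basis is seeded, seed-sensitive and standard normal", {
    b1 <- makeSimHashBasis(10, 4, seed = 7)
    expect_identical(b1, makeSimHashBasis(10, 4, seed = 7))
    expect_false(identical(b1, makeSimHashBasis(10, 4, seed = 8)))
    expect_equal(dim(b1), c(4L, 10L))
    big <- makeSimHashBasis(10000, 1280, seed = 1)
    n <- length(big)
    expect_lt(abs(mean(big)), 3 / sqrt(n))            # SE of the mean
    expect_lt(abs(stats::var(as.vector(big)) - 1), 3 * sqrt(2 / (n - 1)))
    expect_error(makeSimHashBasis(0, 4, seed = 1), "positive")
})

test_that("SimHash bits are dot-product signs, scale-invariant", {
    expect_identical(simhashEncode(c(1, 0), matrix(c(1, 0), nrow = 1)), 1L)
    withr::with_seed(11, {
        x <- stats::rnorm(30)
        basis <- makeSimHashBasis(30, 16, seed = 2)
        bits <- simhashEncode(x, basis)
        loopBits <- integer(16)
        for (p in 1:16) {
            dot <- 0
            for (i in 1:30) dot <- dot + x[i] * basis[p, i]
            loopBits[p] <- if (dot >= 0) 1L else 0L
        }
        expect_identical(bits, loopBits)
        expect_identical(simhashEncode(3.7 * x, basis), bits)
        expect_identical(simhashEncode(0.01 * x, basis), bits)
    })
    expect_error(simhashEncode(1:5, makeSimHashBasis(4, 2, 1)), "mismatch")
})

test_that("sampling plans have floor(alpha d) distinct in-range indices", {
    p <- makeSamplingPlan(10, 5, alpha = 0.1, seed = 3)
    expect_length(p, 5)
    expect_true(all(lengths(p) == 1L))
    full <- makeSamplingPlan(4, 3, alpha = 1.0, seed = 1)
    for (s in full) expect_setequal(s, 1:4)
    big <- makeSamplingPlan(10000, 1280, alpha = 0.1, seed = 11)
    expect_true(all(lengths(big) == 1000L))
    expect_true(all(vapply(big, anyDuplicated, 0L) == 0L))
    expect_true(all(unlist(big) >= 1L & unlist(big) <= 10000L))
    expect_identical(makeSamplingPlan(50, 4, 0.2, seed = 9),
                     makeSamplingPlan(50, 4, 0.2, seed = 9))
    expect_error(makeSamplingPlan(5, 4, alpha = 0.1, seed = 1),
                 "alpha = 0.1, d = 5")
})

test_that("activations are sums over sampled gene sets", {
    p <- structure(list(c(1L, 3L)), d = 3L, alpha = 0.67, seed = 0L)
    expect_equal(computeActivations(c(1, 2, 3), p), 4)
    plan <- makeSamplingPlan(40, 12, 0.25, seed = 5)
    expect_equal(computeActivations(numeric(40) + 0, plan), rep(0, 12))
    withr::with_seed(6, {
        x <- stats::rnorm(40)
        a <- computeActivations(x, plan)
        for (i in seq_along(plan)) {
            s <- 0
            for (j in plan[[i]]) s <- s + x[j]
            expect_equal(a[i], s)
        }
        # matrix fast path agrees with the vector path
        X <- matrix(stats::rnorm(40 * 7), nrow = 40)
        A <- computeActivations(X, plan)
        expect_equal(A[, 3], computeActivations(X[, 3], plan))
    })
    expect_error(computeActivations(c(1, 2), p), "indexes gene")
})

test_that("group partition is a disjoint seeded partition of 1..mk", {
    g1 <- partitionGroups(1, 4, seed = 0)
    expect_setequal(g1[[1]], 1:4)
    g <- partitionGroups(3, 5, seed = 9)
    expect_length(g, 3)
    expect_true(all(lengths(g) == 5L))
    expect_setequal(unlist(g), 1:15)
    expect_identical(partitionGroups(3, 5, seed = 9),
                     partitionGroups(3, 5, seed = 9))
    expect_error(partitionGroups(0, 5, seed = 1), "positive")
})

test_that("FlyHash one-hot blocks match the printed worked examples", {
    g1 <- fixedGroups(1, 5)
    expect_identical(flyhashEncode(c(-3, 1, 2, 4, -1), g1),
                     c(0L, 0L, 0L, 1L, 0L))
    g3 <- fixedGroups(3, 5)
    a <- c(-3, -2, 1, 0, 5, -1, 2, 1, 0, 7, 0, -2, 0, 0, 1)
    expect_identical(flyhashEncode(a, g3),
                     c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L,
                       0L, 0L, 0L, 0L, 1L))
    # ties: the 1 lands on the first (lowest-index) maximum
    expect_identical(flyhashEncode(rep(2, 5), g1), c(1L, 0L, 0L, 0L, 0L))
    expect_error(flyhashEncode(1:4, g1), "length")
})

test_that("DenseFly encodes strict positivity per element", {
    g1 <- fixedGroups(1, 5)
    expect_identical(denseflyEncode(c(-3, 1, 2, 4, -1), g1),
                     c(0L, 1L, 1L, 1L, 0L))
    g3 <- fixedGroups(3, 5)
    a <- c(-3, -2, 1, 0, 5, -1, 2, 1, 0, 7, 0, -2, 0, 0, 1)
    expect_identical(denseflyEncode(a, g3),
                     c(0L, 0L, 1L, 0L, 1L, 0L, 1L, 1L, 0L, 1L,
                       0L, 0L, 0L, 0L, 1L))
    expect_identical(denseflyEncode(rep(0, 5), g1), rep(0L, 5))
})

test_that("pseudo-hash thresholds group sums strictly at zero", {
    g3 <- fixedGroups(3, 5)
    a <- c(-3, -2, 1, 0, 5, -1, 2, 1, 0, 7, 0, -2, 0, 0, 1)
    expect_identical(pseudoHash(a, g3), c(1L, 1L, 0L))
    expect_identical(pseudoHash(c(2, -2, 0, 0, 0), fixedGroups(1, 5)), 0L)
    withr::with_seed(13, {
        groups <- partitionGroups(4, 6, seed = 1)
        a <- stats::rnorm(24)
        bits <- pseudoHash(a, groups)
        for (j in 1:4) {
            s <- 0
            for (i in groups[[j]]) s <- s + a[i]
            expect_identical(bits[j], if (s > 0) 1L else 0L)
        }
    })
})

test_that("encoder properties: weight, purity, pseudo-bit identity", {
    withr::with_seed(21, {
        groups <- partitionGroups(6, 5, seed = 2)
        for (rep in 1:25) {
            a <- stats::rnorm(30)
            fly <- flyhashEncode(a, groups)
            expect_identical(sum(fly), 6L)     # Hamming weight exactly m
            dense <- denseflyEncode(a, groups)
            expect_true(all(dense %in% 0:1))
            ps <- pseudoHash(a, groups)
            for (j in 1:6)
                expect_identical(ps[j],
                                 if (sum(a[groups[[j]]]) > 0) 1L else 0L)
        }
    })
    # repeated full encodings are bit-identical
    x <- matrix(stats::rpois(600, 4), nrow = 30)
    cfg <- HashConfig("densefly", m = 4, k = 8, alpha = 0.2, seed = 5)
    e1 <- encodeCells(x, cfg)
    e2 <- encodeCells(x, cfg)
    expect_identical(e1$long, e2$long)
    expect_identical(e1$short, e2$short)
})

test_that("encodeCells wires centralization, schemes and SimHash widths", {
    withr::with_seed(31, {
        x <- matrix(stats::rpois(50 * 8, 6), nrow = 50)
        colnames(x) <- paste0("c", 1:8)
        cfg <- HashConfig("flyhash", m = 3, k = 4, alpha = 0.3, seed = 7)
        enc <- encodeCells(x, cfg)
        expect_equal(dim(enc$long), c(8L, 12L))
        expect_equal(dim(enc$short), c(8L, 3L))
        # matches the by-hand pipeline on one cell
        xc <- centralizeExpression(x[, 5])
        a <- computeActivations(xc, enc$structures$plan)
        expect_identical(enc$long[5, ],
                         flyhashEncode(a, enc$structures$partition))
        expect_identical(enc$short[5, ],
                         pseudoHash(a, enc$structures$partition))
        # simhash short table equals the long table
        scfg <- HashConfig("simhash", m = 3, k = 4, seed = 7)
        senc <- encodeCells(x, scfg)
        expect_identical(senc$long, senc$short)
        expect_equal(ncol(senc$long), 12L)
        kcfg <- HashConfig("simhash", m = 3, k = 4, seed = 7,
                           simhashBits = "k")
        expect_equal(ncol(encodeCells(x, kcfg)$long), 4L)
    })
})
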