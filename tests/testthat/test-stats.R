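test_that("Kruskal-Wallis matches the rank-sum formula and base R", {
    res <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
    expect_equal(res$statistic, 3.857, tolerance = 5e-4)
    expect_equal(res$statistic, oracleKW(list(c(1, 2, 3), c(4, 5, 6))),
                 tolerance = 1e-10)

    ## total ties: H = 0, P = 1
    res <- kruskalWallis(list(c(2, 2), c(2, 2, 2)))
    expect_equal(res$statistic, 0)
    expect_equal(res$p.value, 1)

    ## label permutation leaves H invariant
    g <- list(a = c(3, 1, 4), b = c(1, 5, 9), c = c(2, 6, 5))
    expect_equal(kruskalWallis(g)$statistic,
                 kruskalWallis(g[c(3, 1, 2)])$statistic)

    ## degenerate groups
    expect_warning(res <- kruskalWallis(list(c(1, 2), c(3, 4), 5)),
                   "fewer than 2")
    expect_error(suppressWarnings(kruskalWallis(list(c(1, 2), 3))),
                 "at least 2 groups")

    ## 100 random small inputs against both oracles
    set.seed(11)
    for (i in 1:100) {
        k <- sample(2:4, 1)
        g <- lapply(seq_len(k), function(j)
            round(rnorm(sample(3:8, 1)), sample(0:2, 1)))
        mine <- kruskalWallis(g)
        ref <- kruskal.test(unlist(g),
                            factor(rep(seq_len(k), lengths(g))))
        expect_equal(mine$statistic, unname(ref$statistic),
                     tolerance = 1e-8)
        expect_equal(mine$p.value, ref$p.value, tolerance = 1e-6)
        expect_equal(mine$statistic, oracleKW(g), tolerance = 1e-8)
    }
})

test_that("BH adjustment is the step-up procedure", {
    expect_equal(bhFDR(0.04), 0.04)
    expect_equal(bhFDR(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_error(bhFDR(c(0.1, NaN)), "missing")
    expect_error(bhFDR(c(0.1, 1.2)), "\\[0, 1\\]")

    set.seed(12)
    for (i in 1:100) {
        p <- runif(sample(1:30, 1))
        adj <- bhFDR(p)
        expect_equal(adj, oracleBH(p), tolerance = 1e-10)
        expect_true(all(adj >= p))
    }

    ## fixed points: fully tied plateaus re-adjust to themselves
    expect_equal(bhFDR(c(0.03, 0.03, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhFDR(bhFDR(c(0.01, 0.02, 0.03))),
                 bhFDR(c(0.01, 0.02, 0.03)))
})

test_that("Spearman correlation matches Pearson-on-ranks", {
    x <- c(1, 2, 3, 4)
    expect_equal(spearmanCor(x, c(10, 20, 21, 40))$statistic, 1)
    expect_equal(spearmanCor(x, c(2, 1, 4, 3))$statistic, 0.6)
    expect_error(spearmanCor(x, rep(2, 4)), "constant")
    expect_error(spearmanCor(x, 1:3), "equal length")

    set.seed(13)
    for (i in 1:100) {
        n <- sample(5:20, 1)
        a <- round(rnorm(n), 1)   # rounding forces ties
        b <- round(rnorm(n), 1)
        if (sd(a) == 0 || sd(b) == 0) next
        mine <- spearmanCor(a, b)
        expect_equal(mine$statistic, oracleSpearman(a, b),
                     tolerance = 1e-8)
        expect_equal(mine$statistic, spearmanCor(b, a)$statistic)
        ref <- suppressWarnings(
            cor.test(a, b, method = "spearman", exact = FALSE))
        expect_equal(mine$p.value, ref$p.value, tolerance = 1e-6)
    }
})

test_that("t-tests match the textbook formulas and handle degeneracy", {
    a <- c(0, 0, 0, 1); b <- c(10, 10, 10, 11)
    mine <- welchTTest(a, b)
    ref <- oracleWelch(a, b)
    expect_equal(mine$statistic, ref$t, tolerance = 1e-10)
    expect_equal(mine$df, ref$df, tolerance = 1e-10)
    expect_equal(mine$p.value, ref$p, tolerance = 1e-10)

    ## identical paired vectors: P = 1 convention, with a warning
    expect_warning(res <- pairedTTest(c(1, 2, 3), c(1, 2, 3)), "convention")
    expect_equal(res$p.value, 1)

    ## exact constant shift: paired P below any threshold
    expect_lt(pairedTTest(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5) - 2)$p.value,
              1e-6)

    set.seed(14)
    for (i in 1:100) {
        n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
        a <- rnorm(n1); b <- rnorm(n2, 0.3)
        mine <- welchTTest(a, b)
        ref <- oracleWelch(a, b)
        expect_equal(mine$statistic, ref$t, tolerance = 1e-8)
        expect_equal(mine$p.value, ref$p, tolerance = 1e-6)
        d <- rnorm(n1)
        mine <- pairedTTest(a, a + d)
        ref <- oraclePaired(a, a + d)
        expect_equal(mine$statistic, ref$t, tolerance = 1e-8)
        expect_equal(mine$p.value, ref$p, tolerance = 1e-6)
    }
})

test_that("parent-offspring regression recovers heritability", {
    x <- rnorm(50)
    expect_equal(parentOffspringH2(x, x)$h2, 1)   # slope 1, clipped at 1

    set.seed(15)
    null <- parentOffspringH2(rnorm(5000), rnorm(5000))
    expect_lt(null$h2, 0.05)

    expect_error(parentOffspringH2(rep(1, 20), rnorm(20)), "constant")
    expect_error(parentOffspringH2(rnorm(5), rnorm(5)), "at least 10")

    ## recovery at h2 = 0.5 over 20 replicates
    est <- sapply(1:20, function(s) {
        d <- simulateParentOffspringPairs(2000, 0.5, seed = 100 + s)
        parentOffspringH2(d$parent, d$offspring)$h2
    })
    expect_lt(abs(mean(est) - 0.5), 0.1)
})
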