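test_that("Bray-Curtis matches its definition and vegan", {
    expect_equal(brayCurtis(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2)), 0)
    expect_equal(brayCurtis(c(1, 0), c(0, 1)), 1)            # disjoint
    expect_equal(brayCurtis(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5)), 0.3)
    expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
    expect_error(brayCurtis(c(1, 2), c(1, 2, 3)), "equal length")

    skip_if_not_installed("vegan")
    set.seed(21)
    for (i in 1:50) {
        x <- randomComposition(sample(3:30, 1))
        y <- randomComposition(length(x))
        d <- brayCurtis(x, y)
        expect_equal(d, oracleBray(x, y), tolerance = 1e-12)
        expect_equal(d, brayCurtis(y, x))                    # symmetry
        expect_true(d >= 0 && d <= 1)                        # bounds
    }
})

test_that("pairwise similarity is computed per pair on labelled subsets", {
    co <- localCohort()
    m <- cohortComponent(co, "mothers")
    o <- cohortComponent(co, "offspring")
    pr <- cohortComponent(co, "pairs")
    pt <- cohortComponent(co, "partition")

    recs <- pairwiseSimilarity(m, o, pr, pt, "heritable")
    expect_identical(nrow(recs), nrow(pairFrame(pr)))        # cardinality
    expect_true(all(recs$similarity >= 0 & recs$similarity <= 1))

    ## identical paired profiles give similarity 1
    copy <- abundances(m)[1:3, , drop = FALSE]
    rownames(copy) <- paste0("copy", 1:3)
    self <- PairMap(sampleIDs(m)[1:3], rownames(copy))
    recs1 <- pairwiseSimilarity(m, AbundanceTable(copy), self, pt,
                                "heritable")
    expect_equal(recs1$similarity, rep(1, 3))

    ## invariant to taxon column ordering
    perm <- sample(taxonIDs(m))
    mP <- AbundanceTable(abundances(m)[, perm])
    expect_equal(pairwiseSimilarity(mP, o, pr, pt, "heritable")$similarity,
                 recs$similarity)

    ## empty labelled overlap is an error
    ptBad <- TaxonPartition(setNames(rep("untracked",
                                         length(taxonIDs(m))),
                                     taxonIDs(m)))
    expect_error(pairwiseSimilarity(m, o, pr, ptBad, "heritable"),
                 "no shared taxa")
})

test_that("keeping compartment mass bounds similarity by the load mismatch", {
    ## one pair, identical within-compartment composition, totals 0.2 vs 0.6
    m <- AbundanceTable(matrix(c(0.1, 0.1, 0.8), 1,
                               dimnames = list("m1", c("h1", "h2", "n1"))))
    o <- AbundanceTable(matrix(c(0.3, 0.3, 0.4), 1,
                               dimnames = list("o1", c("h1", "h2", "n1"))))
    pt <- TaxonPartition(c(h1 = "heritable", h2 = "heritable",
                           n1 = "nonheritable"))
    pr <- PairMap("m1", "o1")
    renorm <- pairwiseSimilarity(m, o, pr, pt, "heritable")$similarity
    raw <- pairwiseSimilarity(m, o, pr, pt, "heritable",
                              renormalize = FALSE)$similarity
    expect_equal(renorm, 1)
    expect_equal(raw, 1 - 0.4 / 0.8)   # |0.2-0.6|/(0.2+0.6)
})

test_that("partition comparison reports Welch P and mean +/- SE", {
    a <- data.frame(similarity = c(0.9, 0.92, 0.95))
    b <- data.frame(similarity = c(0.80, 0.84, 0.85))
    cmp <- comparePartitions(a, b)
    ref <- oracleWelch(a$similarity, b$similarity)
    expect_equal(cmp$test$p.value, ref$p, tolerance = 1e-10)
    expect_equal(cmp$summary$se[1],
                 sd(a$similarity) / sqrt(3), tolerance = 1e-12)

    same <- suppressWarnings(comparePartitions(a, a))
    expect_equal(same$test$p.value, 1)
    expect_error(comparePartitions(a[1, , drop = FALSE], b), "at least 2")
})

test_that("generation totals sum labelled columns per sample", {
    m <- tinyAbundance(c(0.5, 0.5, 0.2, 0.8))
    pt <- TaxonPartition(c(t1 = "heritable", t2 = "nonheritable"))
    gt <- generationTotals(m, pt, "heritable")
    expect_equal(unname(gt$totals), c(0.5, 0.2))   # single-taxon label
    expect_equal(gt$mean, 0.35)
    gtN <- generationTotals(m, pt, "nonheritable")
    expect_equal(unname(gt$totals + gtN$totals), c(1, 1))
})

test_that("flow table ranks by mean mother abundance with stable ties", {
    m <- AbundanceTable(matrix(c(0.2, 0.2, 0.6,
                                 0.4, 0.4, 0.2), 2, byrow = TRUE,
                               dimnames = list(c("m1", "m2"),
                                               c("b", "a", "c"))))
    o <- AbundanceTable(matrix(c(0.1, 0.3, 0.6), 1,
                               dimnames = list("o1", c("b", "a", "c"))))
    pt <- TaxonPartition(c(a = "heritable", b = "heritable",
                           c = "heritable"))
    ft <- flowTable(m, o, pt, "heritable", k = 2)
    ## means: a = 0.3, b = 0.3, c = 0.4 -> c first, then tie a before b
    expect_identical(ft$taxon, c("c", "a"))
    expect_equal(ft$mother_mean, c(0.4, 0.3))
    expect_equal(ft$offspring_mean, c(0.6, 0.3))

    ## k larger than the label: all taxa, no padding
    expect_identical(nrow(flowTable(m, o, pt, "heritable", k = 10)), 3L)

    ## invariant to per-sample permutation
    mP <- AbundanceTable(abundances(m)[c("m2", "m1"), ])
    expect_identical(flowTable(mP, o, pt, "heritable", k = 2)$taxon,
                     ft$taxon)
})
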