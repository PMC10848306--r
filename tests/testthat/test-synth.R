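test_that("simulated genotypes follow HWE and Mendelian transmission", {
    p <- synthParams(nMothers = 10000, nOffspring = 5, nPairs = 5,
                     nNonheritable = 10, nUntracked = 5)
    gt <- simulateGenotypes(p, seed = 1)
    cl <- genotypeCalls(gt)[seq_len(10000), ]

    ## genotype frequencies at maf 0.3: (0.09, 0.42, 0.49) within 3 SE
    snp <- p@snpTable
    for (j in seq_len(nrow(snp))) {
        minor <- snp$effectAllele[j]
        dos <- vapply(strsplit(cl[, snp$snp[j]], ""),
                      function(x) sum(x == minor), 0)
        expected <- c(0.49, 0.42, 0.09)
        for (k in 0:2) {
            pk <- mean(dos == k)
            se <- sqrt(expected[k + 1] * (1 - expected[k + 1]) / 10000)
            expect_lt(abs(pk - expected[k + 1]), 3 * se + 1e-9)
        }
    }

    ## a homozygous mother always passes that allele to her paired offspring
    full <- genotypeCalls(gt)
    pairs <- pairFrame(cohortPairMap(p))
    for (j in snp$snp) {
        mom <- full[pairs$mother, j]
        kid <- full[pairs$offspring, j]
        for (i in seq_along(mom)) {
            al <- strsplit(mom[i], "")[[1]]
            if (al[1] == al[2])
                expect_true(grepl(al[1], kid[i], fixed = TRUE))
        }
    }
})

test_that("every generated abundance row is a valid composition", {
    co <- localCohort()
    m <- abundances(cohortComponent(co, "mothers"))
    o <- abundances(cohortComponent(co, "offspring"))
    expect_true(all(m >= 0) && all(o >= 0))
    expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-8)
    expect_equal(unname(rowSums(o)), rep(1, nrow(o)), tolerance = 1e-8)

    ## untracked block exists only in offspring
    expect_true(any(grepl("^untracked_", colnames(o))))
    expect_false(any(grepl("^untracked_", colnames(m))))
})

test_that("fixing the seed reproduces the cohort exactly", {
    a <- simulateCohort(smallParams(), seed = 7)
    b <- simulateCohort(smallParams(), seed = 7)
    expect_identical(abundances(cohortComponent(a, "mothers")),
                     abundances(cohortComponent(b, "mothers")))
    expect_identical(abundances(cohortComponent(a, "offspring")),
                     abundances(cohortComponent(b, "offspring")))
    expect_identical(genotypeCalls(cohortComponent(a, "genotypes")),
                     genotypeCalls(cohortComponent(b, "genotypes")))
    expect_identical(functionContent(cohortComponent(a, "functions")),
                     functionContent(cohortComponent(b, "functions")))
})

test_that("noiseless transmission gives identical heritable compositions", {
    p <- smallParams(sigmaHeritable = 0)
    p@snpTable$effectSize <- 0    # no genotype-driven divergence either
    co <- simulateCohort(p, seed = 5)
    recs <- pairwiseSimilarity(cohortComponent(co, "mothers"),
                               cohortComponent(co, "offspring"),
                               cohortComponent(co, "pairs"),
                               cohortComponent(co, "partition"),
                               "heritable")
    expect_equal(recs$similarity, rep(1, nrow(recs)), tolerance = 1e-10)
})

test_that("null SNP effects leave the key taxon independent of genotype", {
    p <- smallParams(nMothers = 60)
    p@snpTable$effectSize <- 0
    pvals <- sapply(1:12, function(s) {
        co <- simulateCohort(p, seed = 200 + s)
        rec <- associateTraits(cohortComponent(co, "genotypes"),
                               cohortComponent(co, "mothers"),
                               snpList = "BTB-01532239",
                               traitList = "p-251-o5")
        rec$p_value
    })
    ## raw P approximately uniform: no enrichment of small values
    expect_gt(mean(pvals), 0.2)
    expect_lt(sum(pvals < 0.05), 4)
})

test_that("compartment totals track the configured means", {
    tot <- replicate(6, {
        co <- simulateCohort(smallParams(), seed = sample.int(1e6, 1))
        pt <- cohortComponent(co, "partition")
        c(mh = generationTotals(cohortComponent(co, "mothers"), pt,
                                "heritable")$mean,
          oh = generationTotals(cohortComponent(co, "offspring"), pt,
                                "heritable")$mean,
          on = generationTotals(cohortComponent(co, "offspring"), pt,
                                "nonheritable")$mean)
    })
    expect_lt(abs(mean(tot["mh", ]) - 0.006), 0.0015)
    expect_lt(abs(mean(tot["oh", ]) - 0.007), 0.003)
    expect_lt(abs(mean(tot["on", ]) - 0.577), 0.06)

    ## mothers: heritable + nonheritable close compositionally
    co <- localCohort()
    pt <- cohortComponent(co, "partition")
    th <- generationTotals(cohortComponent(co, "mothers"), pt,
                           "heritable")$totals
    tn <- generationTotals(cohortComponent(co, "mothers"), pt,
                           "nonheritable")$totals
    expect_equal(unname(th + tn), rep(1, length(th)), tolerance = 1e-8)
})

test_that("gene-content matrix obeys its construction constraints", {
    co <- localCohort()
    G <- functionContent(cohortComponent(co, "functions"))
    p <- cohortComponent(co, "params")
    her <- taxaByLabel(cohortComponent(co, "partition"), "heritable")

    ## heritable taxa reach exactly nHeritableFunctions function columns
    expect_equal(sum(colSums(G[her, , drop = FALSE]) > 0),
                 p@nHeritableFunctions)
    ## no all-zero function column, every taxon touches >= 1 function
    expect_true(all(colSums(G) > 0))
    expect_true(all(rowSums(G) > 0))
    ## heritable block is denser than the nonheritable block
    non <- setdiff(rownames(G), her)
    expect_gt(mean(colSums(G[her, seq_len(p@nHeritableFunctions)] > 0)),
              mean(colSums(G[non, ] > 0)))
})

test_that("VFA simulation has the configured structure and signs", {
    co <- localCohort()
    p <- cohortComponent(co, "params")
    m <- cohortComponent(co, "mothers")

    ## zero noise: exactly the stated linear form
    p0 <- p; p0@vfaNoiseSd <- 0
    ph <- phenotypes(simulateVFA(p0, m, seed = 3))
    ab <- abundances(m)
    expected <- p0@vfaIntercepts[["propionate"]] +
        0.8 * log(ab[, "Pseudoscardovia"]) - 0.8 * log(ab[, "p-251-o5"])
    expect_equal(unname(ph[, "propionate"]), unname(expected),
                 tolerance = 1e-12)

    ## zero noise and zero coefficients: constant traits
    p0@vfaTable$coef <- 0
    ph <- phenotypes(simulateVFA(p0, m, seed = 3))
    expect_equal(sd(ph[, "valerate"]), 0)

    ## default params: Pseudoscardovia-propionate association is positive
    signs <- sapply(1:10, function(s) {
        coS <- simulateCohort(smallParams(nMothers = 60), seed = 300 + s)
        spearmanCor(abundances(cohortComponent(coS, "mothers"))[, "Pseudoscardovia"],
                    phenotypes(cohortComponent(coS, "phenotypes"))[, "propionate"]
                    )$statistic
    })
    expect_gte(sum(signs > 0), 9)
})

test_that("similarity calibration brackets, orders and validates", {
    ## fast configuration: small panels, few MC pairs
    p <- smallParams(nNonheritable = 40, nUntracked = 10)
    p@snpTable$effectSize <- 0

    ## perfect transmission: target 1 needs no noise
    expect_equal(calibrateSimilarity(p, "heritable", target = 1,
                                     tol = 0.01, seed = 9,
                                     nPairsMC = 32), 0)

    ## unreachable target reports the attainable range
    expect_error(calibrateSimilarity(p, "heritable", target = 0.05,
                                     tol = 0.01, seed = 9, nPairsMC = 32,
                                     sigmaMax = 0.5),
                 "attainable range")

    ## a lower similarity target needs a larger noise scale, and the
    ## calibrated scale reproduces the target out of sample
    s94 <- calibrateSimilarity(p, "nonheritable", target = 0.94,
                               tol = 0.01, seed = 9, nPairsMC = 64)
    s85 <- calibrateSimilarity(p, "nonheritable", target = 0.85,
                               tol = 0.01, seed = 9, nPairsMC = 64)
    expect_gt(s85, s94)

    p2 <- p; p2@sigmaNonheritable <- s85
    fresh <- sapply(1:6, function(s) {
        co <- simulateCohort(p2, seed = 500 + s)
        mean(pairwiseSimilarity(cohortComponent(co, "mothers"),
                                cohortComponent(co, "offspring"),
                                cohortComponent(co, "pairs"),
                                cohortComponent(co, "partition"),
                                "nonheritable")$similarity)
    })
    expect_lt(abs(mean(fresh) - 0.85), 0.02)
})

test_that("default cohort orders heritable above nonheritable similarity", {
    ord <- sapply(1:5, function(s) {
        co <- simulateCohort(smallParams(), seed = 700 + s)
        m <- cohortComponent(co, "mothers")
        o <- cohortComponent(co, "offspring")
        pr <- cohortComponent(co, "pairs")
        pt <- cohortComponent(co, "partition")
        mean(pairwiseSimilarity(m, o, pr, pt, "heritable")$similarity) >
            mean(pairwiseSimilarity(m, o, pr, pt, "nonheritable")$similarity)
    })
    expect_true(all(ord))
})
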