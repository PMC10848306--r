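test_that("function projection is the renormalized linear map", {
    G <- matrix(c(1, 0, 1, 2), 2,
                dimnames = list(c("t1", "t2"), c("f1", "f2")))
    expect_equal(unname(projectFunctions(c(t1 = 0.5, t2 = 0.5), G)),
                 c(0.25, 0.75))

    ## identity gene content: profile equals the composition
    I3 <- diag(3); dimnames(I3) <- list(letters[1:3], LETTERS[1:3])
    x <- setNames(c(0.2, 0.3, 0.5), letters[1:3])
    expect_equal(unname(projectFunctions(x, I3)), unname(x))

    ## a single shared function collapses every composition to (1)
    G1 <- matrix(1, 3, 1, dimnames = list(letters[1:3], "f"))
    expect_equal(unname(projectFunctions(x, G1)), 1)

    ## no reachable content is an error
    G0 <- matrix(0, 3, 1, dimnames = list(letters[1:3], "f"))
    expect_error(projectFunctions(x, G0), "all-zero")
})

test_that("perturbation measures its realized magnitude", {
    x <- c(0.5, 0.5)
    res <- perturbComposition(x, 0, seed = 1)
    expect_equal(res$t, 0)
    expect_equal(res$perturbed, x)

    ## complete removal of one of two equal taxa: t = 0.5
    expect_equal(brayCurtis(c(0.5, 0.5), c(1, 0)), 0.5)

    ## perturbed vectors stay compositions; E[t] nondecreasing in strength
    set.seed(22)
    x <- randomComposition(20)
    meanT <- sapply(c(0.1, 0.4, 0.8), function(s) {
        mean(replicate(300, {
            r <- perturbComposition(x, s)
            expect_equal(sum(r$perturbed), 1, tolerance = 1e-12)
            r$t
        }))
    })
    expect_true(all(diff(meanT) > 0))
})

test_that("response sampling hits the identity and total-redundancy limits", {
    set.seed(23)
    x <- setNames(randomComposition(6), letters[1:6])
    I6 <- diag(6); dimnames(I6) <- list(letters[1:6], LETTERS[1:6])

    rec <- sampleResponse(x, I6, reps = 5, seed = 2)
    expect_equal(rec$f, rec$t, tolerance = 1e-12)   # functions == taxa

    G1 <- matrix(1, 6, 1, dimnames = list(letters[1:6], "f"))
    rec1 <- sampleResponse(x, G1, reps = 5, seed = 2)
    expect_equal(rec1$f, rep(0, nrow(rec1)))        # perfect buffering

    ## cardinality: strengths x reps minus sub-threshold discards
    rec2 <- sampleResponse(x, I6, reps = 25, seed = 3)
    expect_lte(nrow(rec2), 12 * 25)
    expect_gte(nrow(rec2), 250)

    ## an impossible filter leaves too few records
    expect_error(sampleResponse(x, I6, reps = 1, seed = 2, tMin = 0.99),
                 "fewer than 10")
})

test_that("power-law fitting recovers noiseless coefficients exactly", {
    t <- seq(0.05, 0.9, length.out = 20)

    fit <- fitStability(data.frame(t = t, f = t))
    expect_equal(fit@a, 0, tolerance = 1e-10)
    expect_equal(fit@b, 1, tolerance = 1e-10)
    expect_equal(fit@auc, 0.5, tolerance = 1e-10)

    fit <- fitStability(data.frame(t = t, f = exp(-2) * t^0.5))
    expect_equal(fit@a, 2, tolerance = 1e-10)
    expect_equal(fit@b, 0.5, tolerance = 1e-10)
    expect_equal(fit@auc, exp(-2) / 1.5, tolerance = 1e-10)
    expect_equal(fit@auc, 0.0902, tolerance = 1e-3)

    ## degenerate spread of t
    expect_error(fitStability(data.frame(t = rep(0.5, 12),
                                         f = runif(12))), "degenerate")

    ## symmetric log-space noise leaves the estimates unbiased
    set.seed(24)
    coefs <- replicate(200, {
        f <- exp(-1) * t^0.8 * exp(rnorm(length(t), 0, 0.3))
        ft <- fitStability(data.frame(t = t, f = f))
        c(ft@a, ft@b)
    })
    expect_lt(abs(mean(coefs[1, ]) - 1), 0.02)
    expect_lt(abs(mean(coefs[2, ]) - 0.8), 0.02)
})

test_that("auc always equals the closed form exp(-a)/(b+1)", {
    set.seed(25)
    for (i in 1:20) {
        t <- runif(15, 0.01, 0.95)
        f <- pmin(exp(-runif(1, 0, 2)) * t^runif(1, 0.2, 2) *
                  exp(rnorm(15, 0, 0.2)), 1)
        fit <- fitStability(data.frame(t = t, f = f))
        expect_equal(fit@auc, exp(-fit@a) / (fit@b + 1), tolerance = 1e-12)
    }
})

test_that("cohort stability restricts, renormalizes and reports failures", {
    co <- localCohort()
    m <- cohortComponent(co, "mothers")
    pt <- cohortComponent(co, "partition")
    G <- cohortComponent(co, "functions")

    sub <- AbundanceTable(abundances(m)[1:4, , drop = FALSE])
    fits <- cohortStability(sub, G, pt, "heritable", seed = 6)
    expect_identical(nrow(fits), 4L)
    expect_true(all(fits$auc > 0 & fits$auc < 1))
    expect_true(all(fits$n_points >= 10))

    ## identical inputs and seed give identical fits
    fits2 <- cohortStability(sub, G, pt, "heritable", seed = 6)
    expect_identical(fits, fits2)

    ## G = identity limit: (a, b) -> (0, 1)
    her <- taxaByLabel(pt, "heritable")
    I <- diag(length(her))
    dimnames(I) <- list(her, paste0("F", seq_along(her)))
    fitsI <- cohortStability(sub, FunctionContentMatrix(I), pt,
                             "heritable", seed = 6)
    expect_true(all(abs(fitsI$a) < 0.05))
    expect_true(all(abs(fitsI$b - 1) < 0.05))

    ## a one-taxon sub-community cannot be perturbed after renormalization
    lab <- partitionLabels(pt)
    lab[lab == "heritable"] <- "untracked"
    lab[her[1]] <- "heritable"
    expect_error(suppressWarnings(
        cohortStability(sub, G, TaxonPartition(lab), "heritable",
                        seed = 6)),
        "every sample")
})

test_that("higher functional redundancy lowers the response AUC", {
    set.seed(26)
    wins <- replicate(20, {
        x <- setNames(randomComposition(12), letters[1:12])
        makeG <- function(redundancy) {
            G <- matrix(0, 12, 15,
                        dimnames = list(letters[1:12], paste0("F", 1:15)))
            for (j in 1:15) {
                members <- sample(12, redundancy)
                G[members, j] <- rlnorm(redundancy, 0, 0.5)
            }
            G[rowSums(G) == 0, 1] <- 1
            G
        }
        aucAt <- function(red) {
            rec <- sampleResponse(x, makeG(red), reps = 15,
                                  seed = sample.int(1e6, 1))
            fitStability(rec)@auc
        }
        aucAt(8) < aucAt(2)
    })
    expect_gte(sum(wins), 19)
})

test_that("stability comparison delegates to the right tests", {
    set.seed(27)
    mk <- function(a, b) data.frame(a = a, b = b,
                                    auc = exp(-a) / (b + 1))
    fitsA <- mk(rnorm(10, 1, 0.2), rnorm(10, 1, 0.2))

    same <- suppressWarnings(compareStability(fitsA, fitsA, paired = TRUE))
    expect_equal(same$p_value, rep(1, 3))

    ## a constant shift in b: paired P tiny for b and auc, P = 1 for a
    fitsB <- mk(fitsA$a, fitsA$b + 0.5)
    cmp <- suppressWarnings(compareStability(fitsA, fitsB, paired = TRUE))
    expect_equal(cmp$p_value[cmp$coefficient == "a"], 1)
    expect_lt(cmp$p_value[cmp$coefficient == "b"], 1e-6)
    expect_lt(cmp$p_value[cmp$coefficient == "auc"], 0.01)

    ## unpaired route agrees with the Welch oracle
    fitsC <- mk(rnorm(12, 1.4, 0.3), rnorm(12, 0.8, 0.3))
    cmp <- compareStability(fitsA, fitsC, paired = FALSE)
    ref <- oracleWelch(fitsA$a, fitsC$a)
    expect_equal(cmp$p_value[cmp$coefficient == "a"], ref$p,
                 tolerance = 1e-10)
})
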