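## Taxa-function stability engine: perturb a composition, project taxa to
## functions through a gene-content matrix, measure the functional shift,
## fit the attenuation/buffering power law f = t^b * exp(-a), and summarize
## stability by the closed-form area under the fitted response curve.

#' Project a taxonomic composition into function space
#'
#' The community function profile is the linear gene-content projection
#' \eqn{G^T x}, renormalized to sum 1.
#'
#' @param x named composition vector (or unnamed, matched by position)
#'   indexed by the rows of \code{G}.
#' @param G a \linkS4class{FunctionContentMatrix} or a plain non-negative
#'   taxa x functions matrix.
#' @return named function profile summing to 1.
#' @examples
#' G <- matrix(c(1, 0, 1, 2), 2, dimnames = list(c("t1", "t2"),
#'                                               c("f1", "f2")))
#' projectFunctions(c(t1 = 0.5, t2 = 0.5), G)  # (0.25, 0.75)
#' @export
projectFunctions <- function(x, G) {
    if (is(G, "FunctionContentMatrix")) G <- functionContent(G)
    if (!is.null(names(x))) {
        missing <- setdiff(names(x), rownames(G))
        if (length(missing))
            stop(sprintf("taxa absent from the gene-content matrix: %s",
                         paste(utils::head(missing, 3L), collapse = ", ")))
        G <- G[names(x), , drop = FALSE]
    } else if (length(x) != nrow(G)) {
        stop("composition length does not match the gene-content matrix")
    }
    p <- as.vector(crossprod(G, x))
    s <- sum(p)
    if (s == 0) stop("projection is all-zero: no function content reached")
    stats::setNames(p / s, colnames(G))
}

#' Randomly perturb a composition
#'
#' Each taxon's abundance is multiplied by \eqn{1 - s u_i} with
#' \eqn{u_i \sim} Uniform(0, 1) i.i.d., then the vector is renormalized.
#' The realized taxonomic perturbation magnitude \eqn{t} is measured as
#' the Bray-Curtis distance between the original and perturbed
#' compositions (not assumed from \code{s}).
#'
#' @param x composition vector.
#' @param strength perturbation strength \code{s} in [0, 1].
#' @param seed optional integer seed.
#' @return list with \code{perturbed} (composition) and \code{t}.
#' @export
perturbComposition <- function(x, strength, seed = NULL) {
    stopifnot(strength >= 0, strength <= 1, all(x >= 0), sum(x) > 0)
    run <- function() {
        y <- x * (1 - strength * stats::runif(length(x)))
        y <- y / sum(y)
        list(perturbed = y, t = brayCurtis(x, y))
    }
    if (is.null(seed)) run() else .withSeed(seed, run())
}

#' Sample the taxonomic-perturbation / functional-shift response
#'
#' For every (strength, replicate) combination, perturbs the composition,
#' projects the original and perturbed compositions through \code{G}, and
#' records \code{t} (taxonomic Bray-Curtis) against \code{f} (functional
#' Bray-Curtis). Records with \code{t < tMin} are discarded before fitting.
#'
#' @param x composition vector indexed by the rows of \code{G}.
#' @param G gene-content matrix (see \code{\link{projectFunctions}}).
#' @param strengths grid of perturbation strengths in (0, 1]; default 12
#'   log-spaced values in [0.02, 0.9].
#' @param reps replicates per strength (default 25).
#' @param seed integer seed.
#' @param tMin minimum realized perturbation magnitude kept (default 1e-4).
#' @return data.frame with columns \code{strength}, \code{t}, \code{f};
#'   fewer than 10 surviving records is an error.
#' @export
sampleResponse <- function(x, G, strengths = defaultStrengthGrid(),
                           reps = 25, seed = 1, tMin = 1e-4) {
    stopifnot(all(strengths > 0), all(strengths <= 1), reps >= 1)
    if (is(G, "FunctionContentMatrix")) G <- functionContent(G)
    if (!is.null(names(x))) G <- G[names(x), , drop = FALSE]
    stopifnot(length(x) == nrow(G))
    .withSeed(seed, {
        out <- lapply(strengths, function(s) {
            ## reps perturbed compositions as columns
            U <- matrix(stats::runif(length(x) * reps), length(x), reps)
            P <- x * (1 - s * U)
            P <- sweep(P, 2L, colSums(P), "/")
            tv <- .brayCurtisCols(x, P)
            p0 <- projectFunctions(x, G)
            FP <- crossprod(G, P)
            FP <- sweep(FP, 2L, colSums(FP), "/")
            fv <- .brayCurtisCols(p0, FP)
            data.frame(strength = s, t = tv, f = fv)
        })
        rec <- do.call(rbind, out)
        rec <- rec[rec$t >= tMin, , drop = FALSE]
        if (nrow(rec) < 10L)
            stop("fewer than 10 perturbation records survive the t filter")
        rownames(rec) <- NULL
        rec
    })
}

#' Default perturbation strength grid
#'
#' 12 log-spaced strengths in [0.02, 0.9].
#'
#' @return numeric vector of length 12.
#' @export
defaultStrengthGrid <- function() {
    exp(seq(log(0.02), log(0.9), length.out = 12L))
}

#' Fit the attenuation/buffering power law
#'
#' Ordinary least squares of \eqn{\ln f} on \eqn{\ln t}: the power law
#' \eqn{f = t^b e^{-a}} is linear in logs with slope \eqn{b} (buffering)
#' and intercept \eqn{-a} (attenuation). Functional shifts of exactly 0
#' are floored at \code{fMin} before logging (their count is reported), so
#' perfectly buffered communities produce a large attenuation instead of a
#' fit failure. The area under the fitted response curve on [0, 1] is the
#' closed form \eqn{e^{-a}/(b+1)}.
#'
#' @param records data.frame with columns \code{t} and \code{f} (at least
#'   10 rows with \code{t > 0}).
#' @param fMin floor applied to zero functional shifts (default 1e-6).
#' @return A \linkS4class{StabilityFit}.
#' @examples
#' t <- seq(0.05, 0.9, length.out = 20)
#' fitStability(data.frame(t = t, f = exp(-2) * sqrt(t)))  # a = 2, b = 0.5
#' @export
fitStability <- function(records, fMin = 1e-6) {
    stopifnot(is.data.frame(records), all(c("t", "f") %in% names(records)))
    rec <- records[records$t > 0, , drop = FALSE]
    if (nrow(rec) < 10L)
        stop("at least 10 records with t > 0 are required")
    nFloored <- sum(rec$f < fMin)
    f <- pmax(rec$f, fMin)
    lt <- log(rec$t); lf <- log(f)
    if (stats::var(lt) < 1e-12)
        stop("degenerate perturbation spread: variance of log(t) < 1e-12")
    fit <- stats::lm(lf ~ lt)
    b <- unname(stats::coef(fit)[2L])
    a <- -unname(stats::coef(fit)[1L])
    r2 <- suppressWarnings(summary(fit)$r.squared)  # quiet on perfect fits
    new("StabilityFit", a = a, b = b, auc = exp(-a) / (b + 1),
        nPoints = nrow(rec), rSquared = r2, nFloored = as.integer(nFloored))
}

#' Per-sample taxa-function stability across a cohort
#'
#' For each sample: restrict the composition to the taxa carrying
#' \code{label} (renormalized) and the function columns they touch, sample
#' the perturbation response and fit the power law. Per-sample failures
#' (e.g. degenerate one-taxon sub-communities) are recorded and excluded;
#' all samples failing is an error.
#'
#' @param table an \linkS4class{AbundanceTable}.
#' @param G a \linkS4class{FunctionContentMatrix}.
#' @param partition a \linkS4class{TaxonPartition}.
#' @param label partition label.
#' @param strengths,reps,tMin passed to \code{\link{sampleResponse}}.
#' @param seed integer seed; each sample uses a child seed so results are
#'   independent of sample order.
#' @return data.frame with one row per fitted sample: \code{sample},
#'   \code{a}, \code{b}, \code{auc}, \code{r_squared}, \code{n_points}.
#'   Failed samples are reported in attribute \code{"failures"}.
#' @export
cohortStability <- function(table, G, partition, label,
                            strengths = defaultStrengthGrid(), reps = 25,
                            seed = 1, tMin = 1e-4) {
    stopifnot(is(table, "AbundanceTable"),
              is(G, "FunctionContentMatrix"),
              is(partition, "TaxonPartition"))
    label <- match.arg(label, .partitionLevels)
    taxa <- intersect(intersect(taxaByLabel(partition, label),
                                taxonIDs(table)), taxonIDs(G))
    if (!length(taxa))
        stop(sprintf("no taxa labelled '%s' shared with the gene-content matrix",
                     label))
    g <- functionContent(G)[taxa, , drop = FALSE]
    g <- g[, colSums(g) > 0, drop = FALSE]
    ids <- sampleIDs(table)
    seeds <- .childSeeds(seed, length(ids))
    rows <- vector("list", length(ids))
    failures <- character(0)
    for (i in seq_along(ids)) {
        x <- abundances(table)[ids[i], taxa]
        res <- tryCatch({
            if (sum(x) == 0) stop("empty labelled sub-community")
            x <- x / sum(x)
            rec <- sampleResponse(x, g, strengths, reps, seed = seeds[i],
                                  tMin = tMin)
            fit <- fitStability(rec)
            data.frame(sample = ids[i], a = fit@a, b = fit@b,
                       auc = fit@auc, r_squared = fit@rSquared,
                       n_points = fit@nPoints, stringsAsFactors = FALSE)
        }, error = function(e) {
            failures[[length(failures) + 1L]] <<-
                sprintf("%s: %s", ids[i], conditionMessage(e))
            NULL
        })
        rows[[i]] <- res
    }
    out <- do.call(rbind, rows)
    if (is.null(out) || nrow(out) == 0L)
        stop("stability fitting failed for every sample")
    if (length(failures))
        warning(sprintf("stability fitting skipped %d sample(s)",
                        length(failures)))
    rownames(out) <- NULL
    attr(out, "failures") <- failures
    out
}

#' Compare stability coefficients between two groups of fits
#'
#' Runs a paired t-test (mother vs offspring over aligned pairs) or a
#' Welch t-test (heritable vs nonheritable) separately for the
#' attenuation, buffering and AUC columns, with means and standard errors
#' per group.
#'
#' @param fitsA,fitsB data.frames from \code{\link{cohortStability}}; with
#'   \code{paired = TRUE} rows must be aligned by pair.
#' @param paired logical.
#' @return data.frame with one row per coefficient: means, SEs, statistic,
#'   P value, method.
#' @export
compareStability <- function(fitsA, fitsB, paired = FALSE) {
    stopifnot(all(c("a", "b", "auc") %in% names(fitsA)),
              all(c("a", "b", "auc") %in% names(fitsB)))
    if (paired && nrow(fitsA) != nrow(fitsB))
        stop("paired comparison requires aligned fit lists of equal length")
    rows <- lapply(c("a", "b", "auc"), function(coefName) {
        va <- fitsA[[coefName]]; vb <- fitsB[[coefName]]
        tt <- if (paired) pairedTTest(va, vb) else welchTTest(va, vb)
        data.frame(coefficient = coefName,
                   mean_a = mean(va), se_a = stats::sd(va) / sqrt(length(va)),
                   mean_b = mean(vb), se_b = stats::sd(vb) / sqrt(length(vb)),
                   statistic = tt$statistic, p_value = tt$p.value,
                   method = tt$method, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
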