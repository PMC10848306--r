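## Shared statistical primitives. The tests themselves are delegated to the
## stats package (kruskal.test, cor.test, t.test, p.adjust, lm); this layer
## adds the degenerate-input conventions the pipeline relies on: a
## group-size floor with logged drops, P = 1 for exactly-identical inputs,
## and hard errors on undefined cases instead of silent NaN.

.testResult <- function(statistic, p.value, df, method) {
    structure(list(statistic = unname(statistic),
                   p.value = unname(p.value),
                   df = unname(df), method = method),
              class = "rtTest")
}

#' @export
print.rtTest <- function(x, ...) {
    cat(sprintf("%s: statistic = %.6g, df = %.6g, p = %.4g\n",
                x$method, x$statistic, x$df, x$p.value))
    invisible(x)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with a chi-square P value on k-1 degrees of
#' freedom. Groups with fewer than 2 observations are dropped with a
#' warning; fewer than 2 usable groups is an error. If every observation is
#' identical H = 0 and P = 1.
#'
#' @param groups list of numeric vectors, one per group.
#' @return An \code{rtTest} list: \code{statistic} (H), \code{p.value},
#'   \code{df}, \code{method}.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskalWallis <- function(groups) {
    stopifnot(is.list(groups))
    sizes <- lengths(groups)
    small <- sizes < 2L
    if (any(small)) {
        warning(sprintf("dropping %d group(s) with fewer than 2 observations",
                        sum(small)))
        groups <- groups[!small]
    }
    if (length(groups) < 2L)
        stop("Kruskal-Wallis needs at least 2 groups with >= 2 observations")
    x <- unlist(groups, use.names = FALSE)
    if (anyNA(x) || !all(is.finite(x)))
        stop("observations must be finite and non-missing")
    g <- factor(rep(seq_along(groups), lengths(groups)))
    if (length(unique(x)) == 1L)
        return(.testResult(0, 1, length(groups) - 1L, "Kruskal-Wallis"))
    kt <- stats::kruskal.test(x, g)
    .testResult(kt$statistic, kt$p.value, kt$parameter, "Kruskal-Wallis")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH false-discovery-rate adjustment: monotone, capped at 1,
#' returned in the original input order.
#'
#' @param p numeric vector of raw P values in [0, 1].
#' @return numeric vector of adjusted values (same length and order).
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03))
#' @export
bhFDR <- function(p) {
    if (anyNA(p)) stop("P values must not be missing or NaN")
    if (any(p < 0 | p > 1)) stop("P values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation with t-approximation P value
#'
#' Tie-corrected rho; two-sided P from the asymptotic t approximation.
#' A constant input vector is an error (rho undefined).
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return An \code{rtTest} list with \code{statistic} = rho.
#' @export
spearmanCor <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 4L) stop("at least 4 observations required")
    if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("Spearman correlation is undefined for a constant vector")
    ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE))
    .testResult(ct$estimate, ct$p.value, length(x), "Spearman")
}

#' Welch two-sample t-test
#'
#' Two-sided, unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom. If both samples are constant: P = 1 when the constants agree
#' (with a warning) and P = 0 with an infinite statistic when they differ.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return An \code{rtTest} list.
#' @export
welchTTest <- function(a, b) {
    stopifnot(length(a) >= 2L, length(b) >= 2L)
    if (anyNA(a) || anyNA(b)) stop("missing values are not supported")
    se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    ## same degeneracy criterion t.test uses, resolved by convention
    ## instead of an error
    if (se == 0 || se < 10 * .Machine$double.eps * abs(mean(a) - mean(b))) {
        if (mean(a) == mean(b)) {
            warning("both samples constant and equal; P = 1 by convention")
            return(.testResult(0, 1, length(a) + length(b) - 2L, "Welch t"))
        }
        return(.testResult(Inf, 0, length(a) + length(b) - 2L, "Welch t"))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    .testResult(tt$statistic, tt$p.value, tt$parameter, "Welch t")
}

#' Paired t-test
#'
#' Two-sided paired t-test. If every paired difference is exactly zero,
#' P = 1 by convention (with a warning); if the differences are a nonzero
#' constant the statistic is infinite and P = 0.
#'
#' @param a,b numeric vectors of equal length >= 2, aligned by pair.
#' @return An \code{rtTest} list.
#' @export
pairedTTest <- function(a, b) {
    if (length(a) != length(b)) stop("paired vectors must have equal length")
    stopifnot(length(a) >= 2L)
    if (anyNA(a) || anyNA(b)) stop("missing values are not supported")
    d <- a - b
    se <- stats::sd(d) / sqrt(length(d))
    if (se == 0 || se < 10 * .Machine$double.eps * abs(mean(d))) {
        if (mean(d) == 0) {
            warning("all paired differences are zero; P = 1 by convention")
            return(.testResult(0, 1, length(a) - 1L, "paired t"))
        }
        return(.testResult(sign(mean(d)) * Inf, 0, length(a) - 1L,
                           "paired t"))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    .testResult(tt$statistic, tt$p.value, tt$parameter, "paired t")
}

#' Parent-offspring heritability regression
#'
#' Ordinary least-squares regression of offspring phenotype on a single
#' parent's phenotype; under the additive model the expected slope is
#' \eqn{h^2/2}, so \eqn{h^2} is estimated as twice the slope, clipped to
#' [0, 1]. Only one parent is used (sires unobserved), so midparent
#' regression is not available.
#'
#' @param parent,offspring paired numeric phenotype vectors, length >= 10.
#' @return list with \code{h2}, \code{slope}, \code{se} (standard error of
#'   \code{h2} = 2 x slope SE), \code{nPairs}.
#' @export
parentOffspringH2 <- function(parent, offspring) {
    if (length(parent) != length(offspring))
        stop("parent and offspring vectors must be paired")
    if (length(parent) < 10L) stop("at least 10 pairs are required")
    if (anyNA(parent) || anyNA(offspring))
        stop("missing values are not supported")
    if (stats::sd(parent) == 0)
        stop("heritability regression is undefined for a constant parent vector")
    fit <- stats::lm(offspring ~ parent)
    slope <- unname(stats::coef(fit)[2L])
    se <- unname(suppressWarnings(summary(fit))$coefficients[2L, 2L])
    list(h2 = min(max(2 * slope, 0), 1), slope = slope, se = 2 * se,
         nPairs = length(parent))
}
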