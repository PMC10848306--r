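## Partition-wise mother-offspring compositional similarity, generation
## abundance totals and the top-taxa flow table.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{\sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, bounded in [0, 1] for
#' non-negative vectors. Similarity throughout the package is defined as
#' 1 minus this distance.
#'
#' @param x,y equal-length non-negative numeric vectors, not both all-zero.
#' @return the distance (numeric scalar in [0, 1]).
#' @examples
#' brayCurtis(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5))  # 0.3
#' @export
brayCurtis <- function(x, y) {
    if (length(x) != length(y)) stop("vectors must have equal length")
    if (any(x < 0) || any(y < 0)) stop("vectors must be non-negative")
    tot <- sum(x) + sum(y)
    if (tot == 0) stop("Bray-Curtis is undefined for two all-zero vectors")
    sum(abs(x - y)) / tot
}

## column-wise Bray-Curtis of every column of M against the vector x
.brayCurtisCols <- function(x, M) {
    colSums(abs(M - x)) / (colSums(M) + sum(x))
}

#' Per-pair mother-offspring similarity on a labelled taxon subset
#'
#' For every mother-offspring pair, computes 1 - Bray-Curtis between the
#' two samples restricted to the taxa carrying \code{label} that are
#' present in both tables. By default the sub-vectors are renormalized to
#' compositions before the distance is taken (the standard treatment when
#' a feature table is subset); \code{renormalize = FALSE} keeps the raw
#' compartment masses, in which case differences in total compartment load
#' bound the attainable similarity from above.
#'
#' @param mothers,offspring \linkS4class{AbundanceTable}s.
#' @param pairs a \linkS4class{PairMap} resolving into both tables.
#' @param partition a \linkS4class{TaxonPartition}.
#' @param label \code{"heritable"} or \code{"nonheritable"}.
#' @param renormalize renormalize each sub-vector to sum 1 (default TRUE).
#' @return data.frame with columns \code{pair} (1-based index),
#'   \code{mother}, \code{offspring}, \code{label}, \code{similarity}.
#' @export
pairwiseSimilarity <- function(mothers, offspring, pairs, partition, label,
                               renormalize = TRUE) {
    stopifnot(is(mothers, "AbundanceTable"), is(offspring, "AbundanceTable"),
              is(pairs, "PairMap"), is(partition, "TaxonPartition"))
    label <- match.arg(label, c("heritable", "nonheritable"))
    taxa <- intersect(intersect(taxaByLabel(partition, label),
                                taxonIDs(mothers)), taxonIDs(offspring))
    if (!length(taxa))
        stop(sprintf("no shared taxa labelled '%s' in both tables", label))
    pf <- pairFrame(pairs)
    missM <- setdiff(pf$mother, sampleIDs(mothers))
    missO <- setdiff(pf$offspring, sampleIDs(offspring))
    if (length(missM) || length(missO))
        stop(sprintf("unresolvable pair sample ids: %s",
                     paste(c(missM, missO), collapse = ", ")))
    M <- abundances(mothers)[pf$mother, taxa, drop = FALSE]
    O <- abundances(offspring)[pf$offspring, taxa, drop = FALSE]
    sims <- vapply(seq_len(nrow(pf)), function(i) {
        x <- M[i, ]; y <- O[i, ]
        if (sum(x) == 0 || sum(y) == 0)
            stop(sprintf("pair %d has an empty '%s' sub-community", i,
                         label))
        if (renormalize) { x <- x / sum(x); y <- y / sum(y) }
        1 - brayCurtis(x, y)
    }, 0)
    data.frame(pair = seq_len(nrow(pf)), mother = pf$mother,
               offspring = pf$offspring, label = label, similarity = sims,
               stringsAsFactors = FALSE)
}

#' Compare similarity between the heritable and nonheritable partitions
#'
#' Welch two-sample t-test between the two similarity vectors, with
#' mean and standard error per partition.
#'
#' @param heritableRecords,nonheritableRecords data.frames from
#'   \code{\link{pairwiseSimilarity}} (at least 2 records each).
#' @return list with \code{test} (an \code{rtTest}) and \code{summary}
#'   (data.frame with label, n, mean, se).
#' @export
comparePartitions <- function(heritableRecords, nonheritableRecords) {
    a <- heritableRecords$similarity
    b <- nonheritableRecords$similarity
    if (length(a) < 2L || length(b) < 2L)
        stop("at least 2 similarity records per partition are required")
    summ <- data.frame(
        label = c("heritable", "nonheritable"),
        n = c(length(a), length(b)),
        mean = c(mean(a), mean(b)),
        se = c(stats::sd(a) / sqrt(length(a)),
               stats::sd(b) / sqrt(length(b))))
    list(test = welchTTest(a, b), summary = summ)
}

#' Per-sample total abundance of a labelled compartment
#'
#' Sums the abundances of the taxa carrying \code{label} in each sample,
#' with the cohort mean and standard error. On mothers the heritable and
#' nonheritable totals sum to 1 per sample; on offspring they sum to at
#' most 1 (the remainder is the untracked compartment).
#'
#' @param table an \linkS4class{AbundanceTable}.
#' @param partition a \linkS4class{TaxonPartition}.
#' @param label partition label.
#' @return list with \code{totals} (named numeric per sample), \code{mean}
#'   and \code{se}.
#' @export
generationTotals <- function(table, partition, label) {
    stopifnot(is(table, "AbundanceTable"), is(partition, "TaxonPartition"))
    label <- match.arg(label, .partitionLevels)
    taxa <- intersect(taxaByLabel(partition, label), taxonIDs(table))
    totals <- if (length(taxa))
        rowSums(abundances(table)[, taxa, drop = FALSE])
    else stats::setNames(rep(0, length(sampleIDs(table))), sampleIDs(table))
    list(totals = totals, mean = mean(totals),
         se = stats::sd(totals) / sqrt(length(totals)))
}

#' Top-taxa flow table (Sankey input)
#'
#' Ranks the taxa carrying \code{label} by mean mother abundance (ties
#' broken lexicographically) and exports the per-generation mean
#' abundances of the top \code{k}, the tabular form of a
#' mother-to-offspring flow diagram.
#'
#' @param mothers,offspring \linkS4class{AbundanceTable}s.
#' @param partition a \linkS4class{TaxonPartition}.
#' @param label partition label.
#' @param k number of taxa to keep (default 20; truncated to the number of
#'   labelled taxa present in both tables).
#' @return data.frame with columns \code{taxon}, \code{mother_mean},
#'   \code{offspring_mean}, ordered by decreasing \code{mother_mean}.
#' @export
flowTable <- function(mothers, offspring, partition, label, k = 20) {
    stopifnot(is(mothers, "AbundanceTable"),
              is(offspring, "AbundanceTable"),
              is(partition, "TaxonPartition"), k >= 1)
    label <- match.arg(label, .partitionLevels)
    taxa <- intersect(intersect(taxaByLabel(partition, label),
                                taxonIDs(mothers)), taxonIDs(offspring))
    mm <- colMeans(abundances(mothers)[, taxa, drop = FALSE])
    om <- colMeans(abundances(offspring)[, taxa, drop = FALSE])
    ord <- order(-mm, taxa)
    keep <- ord[seq_len(min(k, length(taxa)))]
    data.frame(taxon = taxa[keep], mother_mean = unname(mm[keep]),
               offspring_mean = unname(om[keep]), stringsAsFactors = FALSE)
}
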