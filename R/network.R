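## Spearman co-abundance network among labelled taxa with strict edge
## thresholds (|rho| > 0.4 and P < 0.05 by default, both strict, no
## multiple-testing correction unless asked for).

#' Build a co-abundance network
#'
#' Tests every unordered pair of taxa carrying \code{label} with Spearman
#' rank correlation across samples and keeps edges with
#' \code{|rho| > rhoThreshold} and \code{p < pThreshold} (strict
#' inequalities). Constant taxon columns are skipped with a warning. No
#' multiple-testing correction is applied by default (raw P thresholding);
#' \code{fdr = TRUE} switches the P filter to BH-adjusted values.
#'
#' @param table an \linkS4class{AbundanceTable} with >= 4 samples.
#' @param partition a \linkS4class{TaxonPartition}.
#' @param label partition label (default \code{"heritable"}).
#' @param rhoThreshold absolute-correlation threshold (default 0.4).
#' @param pThreshold P-value threshold (default 0.05).
#' @param fdr apply BH adjustment across all tested pairs before the P
#'   filter (default FALSE).
#' @return data.frame of edges: \code{taxon_a}, \code{taxon_b} (with
#'   \code{taxon_a < taxon_b} lexicographically), \code{rho}, \code{p};
#'   attribute \code{"taxa"} lists all labelled taxa tested (for degree
#'   summaries over isolated nodes).
#' @export
buildNetwork <- function(table, partition, label = "heritable",
                         rhoThreshold = 0.4, pThreshold = 0.05,
                         fdr = FALSE) {
    stopifnot(is(table, "AbundanceTable"), is(partition, "TaxonPartition"))
    label <- match.arg(label, .partitionLevels)
    taxa <- intersect(taxaByLabel(partition, label), taxonIDs(table))
    if (length(sampleIDs(table)) < 4L)
        stop("at least 4 samples are required")
    if (length(taxa) < 2L)
        stop(sprintf("fewer than 2 taxa labelled '%s'", label))
    ab <- abundances(table)[, taxa, drop = FALSE]
    constant <- taxa[apply(ab, 2L, function(v) stats::sd(v) == 0)]
    if (length(constant)) {
        warning(sprintf("skipping %d constant taxon column(s): %s",
                        length(constant),
                        paste(utils::head(constant, 3L), collapse = ", ")))
        taxa <- setdiff(taxa, constant)
    }
    pairsIdx <- utils::combn(sort(taxa), 2L)
    rows <- lapply(seq_len(ncol(pairsIdx)), function(k) {
        a <- pairsIdx[1L, k]; b <- pairsIdx[2L, k]
        ct <- spearmanCor(ab[, a], ab[, b])
        data.frame(taxon_a = a, taxon_b = b, rho = ct$statistic,
                   p = ct$p.value, stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rows)
    pFilter <- if (fdr) bhFDR(edges$p) else edges$p
    keep <- abs(edges$rho) > rhoThreshold & pFilter < pThreshold
    edges <- edges[keep, , drop = FALSE]
    rownames(edges) <- NULL
    attr(edges, "taxa") <- sort(taxa)
    edges
}

#' Per-taxon degree of a network
#'
#' Degree of every taxon, including isolated taxa at degree 0 when the
#' edge list carries its \code{"taxa"} attribute (or when \code{taxa} is
#' given).
#'
#' @param edges edge data.frame from \code{\link{buildNetwork}}.
#' @param taxa optional character vector of all node ids.
#' @return data.frame with columns \code{taxon} and \code{degree}, sorted
#'   by decreasing degree then taxon id.
#' @export
degreeSummary <- function(edges, taxa = attr(edges, "taxa")) {
    stopifnot(is.data.frame(edges))
    if (is.null(taxa)) taxa <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
    counts <- table(factor(c(edges$taxon_a, edges$taxon_b), levels = taxa))
    out <- data.frame(taxon = names(counts), degree = as.integer(counts),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$degree, out$taxon), , drop = FALSE]
    rownames(out) <- NULL
    out
}
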