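## Readers and writers for every tabular artifact the pipeline touches.
## All formats are tab-delimited UTF-8 text with '#' comment lines; the
## genotype reader additionally understands a minimal VCF 4.2 subset.

#' Read a sample-by-taxon relative abundance table
#'
#' Expects a TSV with a header row of taxon ids and the sample id in the
#' first column (sample-major orientation; use \code{transpose = TRUE} for
#' taxon-major files). Rows whose sums lie within
#' \code{1 +/- renormalizeTolerance} are renormalized to exactly 1; rows
#' summing to about 100 are treated as percentage-scaled and converted to
#' fractions first; anything else is an error naming the offending row.
#' Duplicated sample or taxon names are disambiguated by order of
#' appearance with suffixes \code{"_1"}, \code{"_2"}, ...
#'
#' @param path file path.
#' @param renormalizeTolerance allowed deviation of a row sum from 1 (or
#'   from 100 on the percentage scale) before the row is rejected;
#'   default 0.01.
#' @param transpose logical; set \code{TRUE} when rows are taxa.
#' @return An \linkS4class{AbundanceTable}.
#' @export
readAbundance <- function(path, renormalizeTolerance = 0.01,
                          transpose = FALSE) {
    m <- .frameToMatrix(.readTSV(path))
    if (transpose) m <- t(m)
    if (anyNA(m)) stop("abundance table contains missing values")
    if (any(m < 0)) {
        bad <- which(rowSums(m < 0) > 0)[1L]
        stop(sprintf("negative abundance in row '%s'", rownames(m)[bad]))
    }
    rs <- rowSums(m)
    ## percentage-scaled rows (sum ~ 100) are converted to fractions
    pct <- abs(rs - 100) <= 100 * renormalizeTolerance
    if (any(pct)) {
        m[pct, ] <- m[pct, , drop = FALSE] / 100
        rs <- rowSums(m)
    }
    bad <- which(abs(rs - 1) > renormalizeTolerance)
    if (length(bad))
        stop(sprintf("row '%s' sums to %.6g (outside [%g, %g])",
                     rownames(m)[bad[1L]], rs[bad[1L]],
                     1 - renormalizeTolerance, 1 + renormalizeTolerance))
    AbundanceTable(m / rs)
}

#' Write an AbundanceTable to TSV
#'
#' @param x an \linkS4class{AbundanceTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAbundance <- function(x, path) {
    stopifnot(is(x, "AbundanceTable"))
    .writeTSV(.matrixToFrame(abundances(x), "sample_id"), path)
    invisible(path)
}

#' Read genotype calls
#'
#' Two dialects are supported. \code{"tsv_calls"}: a TSV with sample ids in
#' the first column and one column per SNP holding two-letter allele
#' strings (\code{"GA"} is normalized to \code{"AG"}); empty cells,
#' \code{"NA"}, \code{"--"} or \code{"./."} mean missing. \code{"vcf_min"}:
#' a minimal uncompressed VCF 4.2 subset (CHROM POS ID REF ALT ... GT only),
#' decoded via the vcfR package; \code{"./."} genotypes become missing.
#' A SNP with more than two observed alleles is an error.
#'
#' @param path file path.
#' @param dialect \code{"tsv_calls"} (default) or \code{"vcf_min"}.
#' @return A \linkS4class{GenotypeTable}.
#' @export
readGenotypes <- function(path, dialect = c("tsv_calls", "vcf_min")) {
    dialect <- match.arg(dialect)
    if (dialect == "tsv_calls") {
        df <- .readTSV(path)
        cl <- as.matrix(df[, -1L, drop = FALSE])
        storage.mode(cl) <- "character"
        rownames(cl) <- .disambiguate(df[[1L]])
        colnames(cl) <- .disambiguate(names(df)[-1L])
        cl[cl %in% c("", "NA", "--", "./.", ".")] <- NA_character_
        bad <- !is.na(cl) & !grepl("^[ACGT]{2}$", cl)
        if (any(bad))
            stop(sprintf("malformed genotype call '%s' for sample '%s'",
                         cl[bad][1L],
                         rownames(cl)[which(bad, arr.ind = TRUE)[1L, 1L]]))
        GenotypeTable(cl)
    } else {
        .readVcfMin(path)
    }
}

.readVcfMin <- function(path) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("the 'vcfR' package is required for dialect 'vcf_min'")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    gt <- vcfR::extract.gt(v, element = "GT")
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <-
        paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
    alleles <- cbind(fix[, "REF"], fix[, "ALT"])
    cl <- matrix(NA_character_, ncol(gt), nrow(gt),
                 dimnames = list(colnames(gt), .disambiguate(ids)))
    for (i in seq_len(nrow(gt))) {
        alt <- strsplit(alleles[i, 2L], ",")[[1L]]
        al <- c(alleles[i, 1L], alt)
        if (length(al) > 2L)
            stop(sprintf("SNP '%s' is tri-allelic; only biallelic sites are supported",
                         ids[i]))
        g <- gt[i, ]
        tok <- strsplit(g, "[/|]")
        cl[, i] <- vapply(tok, function(p) {
            if (length(p) != 2L || anyNA(p) || any(p == "."))
                return(NA_character_)
            idx <- suppressWarnings(as.integer(p)) + 1L
            if (anyNA(idx) || any(idx > length(al)))
                stop(sprintf("malformed GT '%s' at SNP '%s'",
                             paste(p, collapse = "/"), ids[i]))
            paste(sort(al[idx]), collapse = "")
        }, "")
    }
    GenotypeTable(cl)
}

#' Write genotype calls to TSV
#'
#' @param x a \linkS4class{GenotypeTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(x, path) {
    stopifnot(is(x, "GenotypeTable"))
    cl <- genotypeCalls(x)
    cl[is.na(cl)] <- "NA"
    .writeTSV(.matrixToFrame(cl, "sample_id"), path)
    invisible(path)
}

#' Read a taxon partition
#'
#' TSV with columns \code{taxon_id} and \code{label} (values
#' \code{heritable}, \code{nonheritable} or \code{untracked}). Duplicated
#' taxon ids are disambiguated by order of appearance.
#'
#' @param path file path.
#' @return A \linkS4class{TaxonPartition}.
#' @export
readPartition <- function(path) {
    df <- .readTSV(path)
    if (!all(c("taxon_id", "label") %in% names(df)))
        stop("partition file needs 'taxon_id' and 'label' columns")
    labels <- df$label
    names(labels) <- .disambiguate(df$taxon_id)
    TaxonPartition(labels)
}

#' Write a taxon partition to TSV
#' @param x a \linkS4class{TaxonPartition}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePartition <- function(x, path) {
    stopifnot(is(x, "TaxonPartition"))
    l <- partitionLabels(x)
    .writeTSV(data.frame(taxon_id = names(l), label = unname(l)), path)
    invisible(path)
}

#' Read a mother-offspring pair map
#'
#' TSV with columns \code{mother} and \code{offspring}.
#'
#' @param path file path.
#' @return A \linkS4class{PairMap}.
#' @export
readPairs <- function(path) {
    df <- .readTSV(path)
    if (!all(c("mother", "offspring") %in% names(df)))
        stop("pair file needs 'mother' and 'offspring' columns")
    PairMap(df$mother, df$offspring)
}

#' Write a pair map to TSV
#' @param x a \linkS4class{PairMap}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePairs <- function(x, path) {
    stopifnot(is(x, "PairMap"))
    .writeTSV(pairFrame(x), path)
    invisible(path)
}

#' Read a taxon-by-function gene-content matrix
#'
#' TSV with taxon ids in the first column and one column per function.
#'
#' @param path file path.
#' @return A \linkS4class{FunctionContentMatrix}.
#' @export
readFunctionMatrix <- function(path) {
    FunctionContentMatrix(.frameToMatrix(.readTSV(path)))
}

#' Write a gene-content matrix to TSV
#' @param x a \linkS4class{FunctionContentMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFunctionMatrix <- function(x, path) {
    stopifnot(is(x, "FunctionContentMatrix"))
    .writeTSV(.matrixToFrame(functionContent(x), "taxon_id"), path)
    invisible(path)
}

#' Read a sample phenotype table
#'
#' TSV with sample ids in the first column and one column per trait
#' (e.g. propionate, valerate). Empty cells and \code{"NA"} are missing.
#'
#' @param path file path.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
readPhenotypes <- function(path) {
    PhenotypeTable(.frameToMatrix(.readTSV(path)))
}

#' Write a phenotype table to TSV
#' @param x a \linkS4class{PhenotypeTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePhenotypes <- function(x, path) {
    stopifnot(is(x, "PhenotypeTable"))
    .writeTSV(.matrixToFrame(phenotypes(x), "sample_id"), path)
    invisible(path)
}

#' Write a co-abundance edge list (Cytoscape-importable)
#'
#' Columns \code{source}, \code{target}, \code{rho}, \code{p}; rows are
#' stably sorted by \code{|rho|} descending. An empty edge set yields a
#' header-only file.
#'
#' @param edges data.frame with columns \code{taxon_a}, \code{taxon_b},
#'   \code{rho}, \code{p} (as produced by \code{\link{buildNetwork}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(edges, path) {
    stopifnot(is.data.frame(edges),
              all(c("taxon_a", "taxon_b", "rho", "p") %in% names(edges)))
    ord <- order(-abs(edges$rho))
    out <- data.frame(source = edges$taxon_a[ord],
                      target = edges$taxon_b[ord],
                      rho = edges$rho[ord], p = edges$p[ord])
    .writeTSV(out, path)
    invisible(path)
}
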