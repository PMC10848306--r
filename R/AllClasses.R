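#' @import methods
NULL

#' Sample-by-taxon relative abundance table
#'
#' Holds a samples x taxa matrix of relative abundances (dimensionless
#' fractions). Every row is a composition: all entries are non-negative and
#' each row sums to 1 within 1e-8. Rows are samples (QIIME2-style transposed
#' feature-table orientation); columns are taxa.
#'
#' @slot values numeric matrix, samples in rows, taxa in columns, with
#'   unique dimnames.
#' @export
setClass("AbundanceTable", representation(values = "matrix"))

setValidity("AbundanceTable", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be a numeric matrix")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        return("values must carry sample (row) and taxon (column) names")
    if (anyDuplicated(rownames(v))) return("duplicated sample ids")
    if (anyDuplicated(colnames(v))) return("duplicated taxon ids")
    if (anyNA(v)) return("abundances must not contain NA")
    if (any(v < 0)) return("abundances must be non-negative")
    rs <- rowSums(v)
    bad <- which(abs(rs - 1) > 1e-8)
    if (length(bad))
        return(sprintf("row '%s' sums to %.6g, not 1", rownames(v)[bad[1L]],
                       rs[bad[1L]]))
    TRUE
})

#' Construct an AbundanceTable
#'
#' @param values numeric matrix (samples x taxa) with dimnames; rows must
#'   already be compositions summing to 1 within 1e-8.
#' @return An \linkS4class{AbundanceTable}.
#' @examples
#' m <- matrix(c(0.5, 0.5, 0.2, 0.8), 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' AbundanceTable(m)
#' @export
AbundanceTable <- function(values) new("AbundanceTable", values = values)

#' Diploid genotype call table
#'
#' Samples x SNP matrix of unordered allele pairs encoded as sorted
#' two-letter strings over \{A,C,G,T\} (e.g. \code{"AG"}); missing calls are
#' \code{NA}, never dropped. Each SNP carries at most two distinct alleles.
#'
#' @slot calls character matrix, samples in rows, SNPs in columns.
#' @export
setClass("GenotypeTable", representation(calls = "matrix"))

setValidity("GenotypeTable", function(object) {
    cl <- object@calls
    if (!is.character(cl)) return("calls must be a character matrix")
    if (is.null(rownames(cl)) || is.null(colnames(cl)))
        return("calls must carry sample (row) and SNP (column) names")
    if (anyDuplicated(rownames(cl))) return("duplicated sample ids")
    if (anyDuplicated(colnames(cl))) return("duplicated SNP ids")
    ok <- is.na(cl) | grepl("^[ACGT]{2}$", cl)
    if (!all(ok)) return("calls must be two-letter ACGT strings or NA")
    nonmiss <- cl[!is.na(cl)]
    if (length(nonmiss) && any(nonmiss != .sortCall(nonmiss)))
        return("allele pairs must be stored in sorted order (e.g. 'AG')")
    for (j in seq_len(ncol(cl))) {
        al <- unique(unlist(strsplit(cl[!is.na(cl[, j]), j], "")))
        if (length(al) > 2L)
            return(sprintf("SNP '%s' carries %d alleles; at most 2 allowed",
                           colnames(cl)[j], length(al)))
    }
    TRUE
})

#' Construct a GenotypeTable
#'
#' @param calls character matrix of two-letter allele-pair strings (order
#'   within the pair is normalized internally) or NA, with dimnames.
#' @return A \linkS4class{GenotypeTable}.
#' @export
GenotypeTable <- function(calls) {
    idx <- !is.na(calls)
    calls[idx] <- .sortCall(calls[idx])
    new("GenotypeTable", calls = calls)
}

.sortCall <- function(x) {
    vapply(strsplit(x, ""), function(p) paste(sort(p), collapse = ""), "")
}

#' Heritable / nonheritable taxon partition
#'
#' Maps each taxon id to one of the labels \code{"heritable"},
#' \code{"nonheritable"} or \code{"untracked"}. The packaged reference
#' partition of the 32 heritable rumen bacteria is available through
#' \code{\link{heritableTaxaReference}}.
#'
#' @slot labels named character vector of labels.
#' @export
setClass("TaxonPartition", representation(labels = "character"))

.partitionLevels <- c("heritable", "nonheritable", "untracked")

setValidity("TaxonPartition", function(object) {
    l <- object@labels
    if (is.null(names(l)) || anyDuplicated(names(l)))
        return("labels must be named by unique taxon ids")
    if (!all(l %in% .partitionLevels))
        return(sprintf("labels must be one of: %s",
                       paste(.partitionLevels, collapse = ", ")))
    TRUE
})

#' Construct a TaxonPartition
#'
#' @param labels named character vector with values in
#'   \code{c("heritable", "nonheritable", "untracked")}.
#' @return A \linkS4class{TaxonPartition}.
#' @export
TaxonPartition <- function(labels) new("TaxonPartition", labels = labels)

#' Mother-offspring sample pairing
#'
#' Records which offspring sample is paired with which mother sample; every
#' cross-generation comparison is driven by this map. No sample id may occur
#' in more than one pair.
#'
#' @slot pairs data.frame with character columns \code{mother} and
#'   \code{offspring}.
#' @export
setClass("PairMap", representation(pairs = "data.frame"))

setValidity("PairMap", function(object) {
    p <- object@pairs
    if (!all(c("mother", "offspring") %in% names(p)))
        return("pairs needs 'mother' and 'offspring' columns")
    ids <- c(p$mother, p$offspring)
    if (anyDuplicated(ids))
        return(sprintf("id '%s' appears in more than one pair",
                       ids[duplicated(ids)][1L]))
    TRUE
})

#' Construct a PairMap
#'
#' @param mother,offspring character vectors of equal length giving the
#'   paired sample ids.
#' @return A \linkS4class{PairMap}.
#' @export
PairMap <- function(mother, offspring) {
    new("PairMap", pairs = data.frame(mother = as.character(mother),
                                      offspring = as.character(offspring),
                                      stringsAsFactors = FALSE))
}

#' Taxon-by-function gene-content matrix
#'
#' Non-negative gene-content weights linking taxa (rows) to predicted
#' biological functions (columns); the abstraction of a PICRUSt2-style
#' prediction. Community function profiles are obtained by the linear
#' projection \code{t(G) \%*\% x} (see \code{\link{projectFunctions}}).
#'
#' @slot counts numeric matrix, taxa in rows, functions in columns.
#' @export
setClass("FunctionContentMatrix", representation(counts = "matrix"))

setValidity("FunctionContentMatrix", function(object) {
    g <- object@counts
    if (!is.numeric(g)) return("counts must be a numeric matrix")
    if (is.null(rownames(g)) || is.null(colnames(g)))
        return("counts must carry taxon (row) and function (column) names")
    if (anyDuplicated(rownames(g))) return("duplicated taxon ids")
    if (anyDuplicated(colnames(g))) return("duplicated function ids")
    if (anyNA(g) || any(g < 0)) return("gene-content weights must be >= 0")
    TRUE
})

#' Construct a FunctionContentMatrix
#'
#' @param counts non-negative numeric matrix (taxa x functions) with dimnames.
#' @return A \linkS4class{FunctionContentMatrix}.
#' @export
FunctionContentMatrix <- function(counts)
    new("FunctionContentMatrix", counts = counts)

#' Sample phenotype table (volatile fatty acids)
#'
#' Samples x traits matrix of phenotype measurements, e.g. rumen propionate
#' and valerate concentrations. Values are finite or explicitly missing (NA).
#'
#' @slot values numeric matrix, samples in rows, traits in columns.
#' @export
setClass("PhenotypeTable", representation(values = "matrix"))

setValidity("PhenotypeTable", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be a numeric matrix")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        return("values must carry sample (row) and trait (column) names")
    if (anyDuplicated(rownames(v))) return("duplicated sample ids")
    if (anyDuplicated(colnames(v))) return("duplicated trait names")
    if (any(!is.na(v) & !is.finite(v)))
        return("phenotype values must be finite or NA")
    TRUE
})

#' Construct a PhenotypeTable
#'
#' @param values numeric matrix (samples x traits) with dimnames.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
PhenotypeTable <- function(values) new("PhenotypeTable", values = values)

#' Fitted taxa-function stability coefficients
#'
#' Result of fitting the power law \eqn{f = t^b e^{-a}} relating taxonomic
#' perturbation magnitude \eqn{t} to functional shift \eqn{f} for one
#' community: attenuation \eqn{a}, buffering \eqn{b}, and the area under the
#' fitted response curve on \eqn{t \in [0,1]}, which is
#' \eqn{e^{-a}/(b+1)} in closed form. Larger \eqn{a} and \eqn{b} (hence
#' smaller AUC) mean a more stable community function.
#'
#' @slot a attenuation coefficient (dimensionless).
#' @slot b buffering coefficient (dimensionless).
#' @slot auc area under the fitted response curve; always equals
#'   \code{exp(-a) / (b + 1)}.
#' @slot nPoints number of perturbation records used in the fit.
#' @slot rSquared coefficient of determination of the log-log regression.
#' @slot nFloored number of zero functional shifts floored before logging.
#' @export
setClass("StabilityFit",
         representation(a = "numeric", b = "numeric", auc = "numeric",
                        nPoints = "integer", rSquared = "numeric",
                        nFloored = "integer"))

setValidity("StabilityFit", function(object) {
    if (length(object@a) != 1L || !is.finite(object@a))
        return("a must be a finite scalar")
    if (length(object@b) != 1L || !is.finite(object@b))
        return("b must be a finite scalar")
    if (object@nPoints < 10L)
        return("a reported fit requires at least 10 perturbation records")
    if (abs(object@auc - exp(-object@a) / (object@b + 1)) > 1e-12)
        return("auc must equal exp(-a)/(b+1)")
    TRUE
})

#' Simulated paired-cohort bundle
#'
#' Everything one simulated study produces: mother and offspring abundance
#' tables, genotypes for both generations, the mother-offspring pair map,
#' the taxon partition, a taxon-function gene-content matrix, mother VFA
#' phenotypes, and a ground-truth record of every generative parameter
#' (sufficient to score any recovery experiment without re-simulation).
#'
#' @slot mothers,offspring \linkS4class{AbundanceTable}s. Offspring carry an
#'   extra block of \code{untracked_*} taxa absent from mothers.
#' @slot genotypes \linkS4class{GenotypeTable} covering both generations.
#' @slot pairs \linkS4class{PairMap}.
#' @slot partition \linkS4class{TaxonPartition}.
#' @slot functions \linkS4class{FunctionContentMatrix}.
#' @slot phenotypes \linkS4class{PhenotypeTable} (mother VFAs).
#' @slot groundTruth list of generative parameters (baselines, SNP effects,
#'   per-sample compartment totals, noise scales).
#' @slot params the \linkS4class{SynthParams} used.
#' @export
setClass("SynthCohort",
         representation(mothers = "AbundanceTable",
                        offspring = "AbundanceTable",
                        genotypes = "GenotypeTable",
                        pairs = "PairMap",
                        partition = "TaxonPartition",
                        functions = "FunctionContentMatrix",
                        phenotypes = "PhenotypeTable",
                        groundTruth = "list",
                        params = "ANY"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "AbundanceTable", function(object) {
    cat(sprintf("AbundanceTable: %d samples x %d taxa\n",
                nrow(object@values), ncol(object@values)))
})

setMethod("show", "GenotypeTable", function(object) {
    cat(sprintf("GenotypeTable: %d samples x %d SNPs (%d missing calls)\n",
                nrow(object@calls), ncol(object@calls),
                sum(is.na(object@calls))))
})

setMethod("show", "TaxonPartition", function(object) {
    tab <- table(factor(object@labels, levels = .partitionLevels))
    cat(sprintf("TaxonPartition: %d heritable, %d nonheritable, %d untracked\n",
                tab[["heritable"]], tab[["nonheritable"]],
                tab[["untracked"]]))
})

setMethod("show", "PairMap", function(object) {
    cat(sprintf("PairMap: %d mother-offspring pairs\n", nrow(object@pairs)))
})

setMethod("show", "FunctionContentMatrix", function(object) {
    cat(sprintf("FunctionContentMatrix: %d taxa x %d functions (%.1f%% nonzero)\n",
                nrow(object@counts), ncol(object@counts),
                100 * mean(object@counts > 0)))
})

setMethod("show", "PhenotypeTable", function(object) {
    cat(sprintf("PhenotypeTable: %d samples x %d traits\n",
                nrow(object@values), ncol(object@values)))
})

setMethod("show", "StabilityFit", function(object) {
    cat(sprintf(
        "StabilityFit: a = %.4f, b = %.4f, auc = %.4f (n = %d, R2 = %.3f)\n",
        object@a, object@b, object@auc, object@nPoints, object@rSquared))
})

setMethod("show", "SynthCohort", function(object) {
    cat("SynthCohort\n")
    cat("  mothers:   "); show(object@mothers)
    cat("  offspring: "); show(object@offspring)
    cat("  genotypes: "); show(object@genotypes)
    cat("  pairs:     "); show(object@pairs)
})
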