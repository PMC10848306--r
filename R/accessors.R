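## Accessor generics and methods. Slots are never reached into by user code;
## these are the supported surface.

#' Sample identifiers of a container
#' @param x an object with samples.
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Taxon identifiers of a container
#' @param x an object with taxa.
#' @return character vector of taxon ids.
#' @export
setGeneric("taxonIDs", function(x) standardGeneric("taxonIDs"))

#' Relative-abundance matrix of an AbundanceTable
#' @param x an \linkS4class{AbundanceTable}.
#' @return numeric matrix (samples x taxa).
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @describeIn sampleIDs samples of an abundance table.
#' @export
setMethod("sampleIDs", "AbundanceTable", function(x) rownames(x@values))

#' @describeIn taxonIDs taxa of an abundance table.
#' @export
setMethod("taxonIDs", "AbundanceTable", function(x) colnames(x@values))

#' @describeIn abundances the underlying matrix.
#' @export
setMethod("abundances", "AbundanceTable", function(x) x@values)

#' Genotype call matrix
#' @param x a \linkS4class{GenotypeTable}.
#' @return character matrix of sorted allele-pair strings (NA = missing).
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @describeIn genotypeCalls the underlying call matrix.
#' @export
setMethod("genotypeCalls", "GenotypeTable", function(x) x@calls)

#' SNP identifiers
#' @param x a \linkS4class{GenotypeTable}.
#' @return character vector of SNP ids.
#' @export
setGeneric("snpIDs", function(x) standardGeneric("snpIDs"))

#' @describeIn snpIDs SNP columns of a genotype table.
#' @export
setMethod("snpIDs", "GenotypeTable", function(x) colnames(x@calls))

#' @describeIn sampleIDs samples of a genotype table.
#' @export
setMethod("sampleIDs", "GenotypeTable", function(x) rownames(x@calls))

#' Observed alleles at one SNP
#'
#' @param x a \linkS4class{GenotypeTable}.
#' @param snp SNP id.
#' @return character vector of the distinct alleles observed (sorted).
#' @export
snpAlleles <- function(x, snp) {
    stopifnot(is(x, "GenotypeTable"))
    if (!snp %in% snpIDs(x)) stop(sprintf("unknown SNP '%s'", snp))
    cl <- x@calls[, snp]
    sort(unique(unlist(strsplit(cl[!is.na(cl)], ""))))
}

#' Partition labels
#' @param x a \linkS4class{TaxonPartition}.
#' @return named character vector of labels.
#' @export
setGeneric("partitionLabels", function(x) standardGeneric("partitionLabels"))

#' @describeIn partitionLabels the named label vector.
#' @export
setMethod("partitionLabels", "TaxonPartition", function(x) x@labels)

#' Taxa carrying a given partition label
#'
#' @param partition a \linkS4class{TaxonPartition}.
#' @param label one of \code{"heritable"}, \code{"nonheritable"},
#'   \code{"untracked"}.
#' @return character vector of taxon ids.
#' @export
taxaByLabel <- function(partition, label) {
    stopifnot(is(partition, "TaxonPartition"))
    label <- match.arg(label, .partitionLevels)
    names(partition@labels)[partition@labels == label]
}

#' Pairs of a PairMap
#' @param x a \linkS4class{PairMap}.
#' @return data.frame with columns \code{mother} and \code{offspring}.
#' @export
setGeneric("pairFrame", function(x) standardGeneric("pairFrame"))

#' @describeIn pairFrame the pair data.frame.
#' @export
setMethod("pairFrame", "PairMap", function(x) x@pairs)

#' Gene-content matrix
#' @param x a \linkS4class{FunctionContentMatrix}.
#' @return numeric matrix (taxa x functions).
#' @export
setGeneric("functionContent", function(x) standardGeneric("functionContent"))

#' @describeIn functionContent the underlying matrix.
#' @export
setMethod("functionContent", "FunctionContentMatrix", function(x) x@counts)

#' @describeIn taxonIDs taxa of a gene-content matrix.
#' @export
setMethod("taxonIDs", "FunctionContentMatrix", function(x) rownames(x@counts))

#' Function identifiers
#' @param x a \linkS4class{FunctionContentMatrix}.
#' @return character vector of function ids.
#' @export
setGeneric("functionIDs", function(x) standardGeneric("functionIDs"))

#' @describeIn functionIDs function columns.
#' @export
setMethod("functionIDs", "FunctionContentMatrix", function(x)
    colnames(x@counts))

#' Phenotype matrix
#' @param x a \linkS4class{PhenotypeTable}.
#' @return numeric matrix (samples x traits).
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @describeIn phenotypes the underlying matrix.
#' @export
setMethod("phenotypes", "PhenotypeTable", function(x) x@values)

#' @describeIn sampleIDs samples of a phenotype table.
#' @export
setMethod("sampleIDs", "PhenotypeTable", function(x) rownames(x@values))

#' Stability coefficients of a fit
#' @param x a \linkS4class{StabilityFit}.
#' @return named numeric vector \code{c(a, b, auc, rSquared, nPoints)}.
#' @export
stabilityCoefficients <- function(x) {
    stopifnot(is(x, "StabilityFit"))
    c(a = x@a, b = x@b, auc = x@auc, rSquared = x@rSquared,
      nPoints = as.numeric(x@nPoints))
}

#' Components of a SynthCohort
#'
#' @param x a \linkS4class{SynthCohort}.
#' @param name one of \code{"mothers"}, \code{"offspring"},
#'   \code{"genotypes"}, \code{"pairs"}, \code{"partition"},
#'   \code{"functions"}, \code{"phenotypes"}, \code{"groundTruth"},
#'   \code{"params"}.
#' @return the requested component.
#' @export
cohortComponent <- function(x, name) {
    stopifnot(is(x, "SynthCohort"))
    name <- match.arg(name, c("mothers", "offspring", "genotypes", "pairs",
                              "partition", "functions", "phenotypes",
                              "groundTruth", "params"))
    slot(x, name)
}
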