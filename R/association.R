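## Genotype-class association between SNPs and taxon abundances or VFA
## concentrations: Kruskal-Wallis across observed genotype classes, BH
## false-discovery adjustment per trait across SNPs, and the two-tier
## significance call (FDR < 0.01 significant, 0.01 <= FDR < 0.05
## suggestive).

#' Encode reference-allele dosage
#'
#' Counts copies of \code{referenceAllele} per sample at one SNP:
#' AA -> 2, AG -> 1, GG -> 0 for reference A. Missing calls propagate as
#' NA. The complementarity \code{dosage(ref = A) + dosage(ref = G) = 2}
#' holds per non-missing sample at a biallelic site.
#'
#' @param genotypes a \linkS4class{GenotypeTable}.
#' @param snp SNP id.
#' @param referenceAllele single allele letter; must be observed at the SNP.
#' @return named integer vector of dosages (NA = missing call).
#' @export
encodeDosage <- function(genotypes, snp, referenceAllele) {
    stopifnot(is(genotypes, "GenotypeTable"))
    obs <- snpAlleles(genotypes, snp)
    if (!referenceAllele %in% obs)
        stop(sprintf("allele '%s' is not observed at SNP '%s' (alleles: %s)",
                     referenceAllele, snp, paste(obs, collapse = ", ")))
    cl <- genotypeCalls(genotypes)[, snp]
    d <- vapply(strsplit(cl, ""), function(p) {
        if (anyNA(p)) NA_integer_ else sum(p == referenceAllele)
    }, 1L)
    d[is.na(cl)] <- NA_integer_
    stats::setNames(d, rownames(genotypeCalls(genotypes)))
}

.traitMatrix <- function(traits) {
    if (is(traits, "AbundanceTable")) abundances(traits)
    else if (is(traits, "PhenotypeTable")) phenotypes(traits)
    else if (is.matrix(traits)) traits
    else stop("traits must be an AbundanceTable, PhenotypeTable or matrix")
}

.tierOf <- function(fdr) {
    ifelse(fdr < 0.01, "significant",
           ifelse(fdr < 0.05, "suggestive", "ns"))
}

#' SNP-by-trait Kruskal-Wallis association scan
#'
#' For each SNP x trait combination, groups samples by genotype class
#' (e.g. AA / AG / GG), drops classes with fewer than 2 samples, and runs
#' the Kruskal-Wallis test across the remaining classes. P values are
#' BH-adjusted per trait across the tested SNPs, and the two-tier
#' significance call is assigned from the adjusted value (strictly below
#' 0.01: significant; in [0.01, 0.05): suggestive; otherwise ns).
#'
#' @param genotypes a \linkS4class{GenotypeTable}.
#' @param traits an \linkS4class{AbundanceTable} or
#'   \linkS4class{PhenotypeTable} (samples must overlap the genotypes).
#' @param snpList SNP ids to test (default: all).
#' @param traitList trait/taxon ids to test (default: all).
#' @return data.frame with one row per SNP x trait: \code{snp},
#'   \code{trait}, \code{classes} (comma-joined genotype classes used),
#'   \code{n}, \code{statistic}, \code{p_value}, \code{fdr}, \code{tier}.
#' @export
associateTraits <- function(genotypes, traits, snpList = snpIDs(genotypes),
                            traitList = NULL) {
    stopifnot(is(genotypes, "GenotypeTable"))
    tm <- .traitMatrix(traits)
    if (is.null(traitList)) traitList <- colnames(tm)
    shared <- intersect(rownames(genotypeCalls(genotypes)), rownames(tm))
    if (length(shared) < 4L)
        stop("fewer than 4 samples shared between genotypes and traits")
    cl <- genotypeCalls(genotypes)[shared, snpList, drop = FALSE]
    tm <- tm[shared, traitList, drop = FALSE]

    rows <- list()
    for (trait in traitList) {
        for (snp in snpList) {
            g <- cl[, snp]
            v <- tm[, trait]
            ok <- !is.na(g) & !is.na(v)
            groups <- split(v[ok], g[ok])
            groups <- groups[lengths(groups) >= 2L]
            if (length(groups) < 2L)
                stop(sprintf(
                    "SNP '%s' x trait '%s': fewer than 2 genotype classes with >= 2 samples",
                    snp, trait))
            kt <- kruskalWallis(groups)
            rows[[length(rows) + 1L]] <- data.frame(
                snp = snp, trait = trait,
                classes = paste(names(groups), collapse = ","),
                n = sum(lengths(groups)), statistic = kt$statistic,
                p_value = kt$p.value, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out$fdr <- NA_real_
    for (trait in unique(out$trait)) {
        idx <- out$trait == trait
        out$fdr[idx] <- bhFDR(out$p_value[idx])
    }
    out$tier <- .tierOf(out$fdr)
    rownames(out) <- NULL
    out
}

#' Direction of a dosage-trait effect
#'
#' Sign of the Spearman correlation between reference-allele dosage and a
#' trait; +1 means the reference allele raises the trait. Swapping the
#' reference allele flips the sign.
#'
#' @param dosage numeric dosage vector (from \code{\link{encodeDosage}}).
#' @param traitValues numeric trait vector aligned with \code{dosage}.
#' @return -1, 0 or +1.
#' @export
directionOfEffect <- function(dosage, traitValues) {
    if (length(dosage) != length(traitValues))
        stop("dosage and trait vectors must be aligned")
    ok <- !is.na(dosage) & !is.na(traitValues)
    dosage <- dosage[ok]; traitValues <- traitValues[ok]
    if (stats::sd(traitValues) == 0)
        stop("direction is undefined for a constant trait")
    if (length(unique(dosage)) < 2L)
        stop("at least 2 distinct dosage values are required")
    sign(spearmanCor(as.numeric(dosage), traitValues)$statistic)
}

#' Cross-generation genotype and key-taxon comparison
#'
#' For each key SNP: the genotype-class frequency table per generation
#' (frequencies sum to 1 within each generation). For each key taxon: a
#' paired t-test of its relative abundance between mothers and their
#' paired offspring.
#'
#' @param genotypes a \linkS4class{GenotypeTable} covering both
#'   generations.
#' @param mothers,offspring \linkS4class{AbundanceTable}s.
#' @param pairs a \linkS4class{PairMap}.
#' @param keyTaxa character vector of taxon ids present in both tables.
#' @param keySnps character vector of SNP ids.
#' @return list with \code{genotypeFrequencies} (data.frame: snp,
#'   generation, class, frequency) and \code{taxonComparisons} (data.frame:
#'   taxon, mother mean, offspring mean, statistic, P).
#' @export
crossGenerationComparison <- function(genotypes, mothers, offspring, pairs,
                                      keyTaxa, keySnps) {
    stopifnot(is(genotypes, "GenotypeTable"), is(mothers, "AbundanceTable"),
              is(offspring, "AbundanceTable"), is(pairs, "PairMap"))
    missT <- setdiff(keyTaxa, intersect(taxonIDs(mothers),
                                        taxonIDs(offspring)))
    if (length(missT))
        stop(sprintf("key taxa unresolved in both tables: %s",
                     paste(missT, collapse = ", ")))
    missS <- setdiff(keySnps, snpIDs(genotypes))
    if (length(missS))
        stop(sprintf("key SNPs unresolved: %s",
                     paste(missS, collapse = ", ")))
    pf <- pairFrame(pairs)
    cl <- genotypeCalls(genotypes)

    freq <- list()
    for (snp in keySnps) {
        for (gen in c("mother", "offspring")) {
            ids <- intersect(if (gen == "mother") sampleIDs(mothers)
                             else sampleIDs(offspring), rownames(cl))
            g <- cl[ids, snp]
            tab <- table(g[!is.na(g)])
            if (!length(tab)) next   # no genotyped samples this generation
            freq[[length(freq) + 1L]] <- data.frame(
                snp = snp, generation = gen, class = names(tab),
                frequency = as.numeric(tab) / sum(tab),
                stringsAsFactors = FALSE)
        }
    }

    cmp <- lapply(keyTaxa, function(taxon) {
        vm <- abundances(mothers)[pf$mother, taxon]
        vo <- abundances(offspring)[pf$offspring, taxon]
        tt <- pairedTTest(vm, vo)
        data.frame(taxon = taxon, mother_mean = mean(vm),
                   offspring_mean = mean(vo), statistic = tt$statistic,
                   p_value = tt$p.value, stringsAsFactors = FALSE)
    })
    list(genotypeFrequencies = do.call(rbind, freq),
         taxonComparisons = do.call(rbind, cmp))
}
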