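## Synthetic paired-cohort generator. The defaults ARE the study conditions:
## 254 mothers, 107 offspring, 17 pairs, 32 heritable + 674 tracked
## nonheritable taxa, 5 causal SNPs on 2 key taxa, 191 of 236 functions
## reachable from heritable taxa, compartment totals 0.006/0.007/0.994/0.577
## and partition similarity targets 0.94/0.85.

#' Parameters of the synthetic paired cohort
#'
#' All knobs of the generator, pre-set to the study's printed cohort
#' characteristics. Transmission-noise scales (\code{sigmaHeritable},
#' \code{sigmaNonheritable}) default to values calibrated with
#' \code{\link{calibrateSimilarity}} so that the default cohort reproduces
#' the partition similarity targets in expectation.
#'
#' @slot nMothers,nOffspring,nPairs cohort sizes (254 / 107 / 17).
#' @slot nHeritable,nNonheritable,nUntracked taxon-panel sizes; the
#'   untracked block exists only in offspring and fills the compositional
#'   remainder.
#' @slot nFunctions,nHeritableFunctions total predicted functions (236) and
#'   the subset reachable from heritable taxa (191).
#' @slot h2KeyTaxon narrow-sense heritability of the key taxa on the
#'   log-abundance scale (0.79).
#' @slot motherHeritableTotal,offspringHeritableTotal,motherNonheritableTotal,offspringTrackedNonheritableTotal
#'   expected compartment totals (0.006 / 0.007 / 0.994 / 0.577).
#' @slot targetSimHeritable,targetSimNonheritable mother-offspring
#'   similarity targets used by the calibration (0.94 / 0.85).
#' @slot sigmaHeritable,sigmaNonheritable lognormal transmission-noise
#'   scales for the heritable and tracked-nonheritable blocks.
#' @slot cvMotherHeritableTotal,cvOffspringHeritableTotal,cvTrackedTotal
#'   log-sd of the per-sample compartment-total jitters (chosen so the
#'   simulated cohort SEs are of the same order as the printed ones).
#' @slot baselineSdHeritable,baselineSdNonheritable,baselineSdUntracked
#'   log-sd of the between-taxon baseline spread.
#' @slot taxonLogSd per-sample log-abundance noise of ordinary taxa.
#' @slot redundancyHeritable,redundancyNonheritable mean taxa per function
#'   in the two gene-content blocks; heritable must exceed nonheritable.
#' @slot snpTable data.frame describing the causal SNPs: id, the two
#'   alleles, minor-allele frequency, effect allele, per-copy log-abundance
#'   effect, and the key taxon affected.
#' @slot vfaTable data.frame of signed taxon-to-VFA coefficients.
#' @slot vfaIntercepts,vfaNoiseSd VFA intercepts (arbitrary concentration
#'   units) and Gaussian noise sd.
#' @slot seed default master seed.
#' @export
setClass("SynthParams", representation(
    nMothers = "numeric", nOffspring = "numeric", nPairs = "numeric",
    nHeritable = "numeric", nNonheritable = "numeric",
    nUntracked = "numeric",
    nFunctions = "numeric", nHeritableFunctions = "numeric",
    h2KeyTaxon = "numeric",
    motherHeritableTotal = "numeric", offspringHeritableTotal = "numeric",
    motherNonheritableTotal = "numeric",
    offspringTrackedNonheritableTotal = "numeric",
    targetSimHeritable = "numeric", targetSimNonheritable = "numeric",
    sigmaHeritable = "numeric", sigmaNonheritable = "numeric",
    cvMotherHeritableTotal = "numeric",
    cvOffspringHeritableTotal = "numeric", cvTrackedTotal = "numeric",
    baselineSdHeritable = "numeric", baselineSdNonheritable = "numeric",
    baselineSdUntracked = "numeric", taxonLogSd = "numeric",
    redundancyHeritable = "numeric", redundancyNonheritable = "numeric",
    snpTable = "data.frame", vfaTable = "data.frame",
    vfaIntercepts = "numeric", vfaNoiseSd = "numeric", seed = "numeric"))

.defaultSnpTable <- function() {
    data.frame(
        snp = c("BTB-01532239", "ARS-BFGL-NGS-8960", "BTB-00740910",
                "BovineHD1900005868", "BovineHD1300021786"),
        alleleA = c("A", "G", "G", "A", "G"),
        alleleB = c("G", "A", "A", "G", "A"),
        maf = c(0.30, 0.30, 0.30, 0.30, 0.30),
        effectAllele = c("G", "A", "A", "G", "A"),
        effectSize = c(0.6, 0.6, 0.6, 0.6, 0.6),
        taxon = c("p-251-o5", "p-251-o5", "Pseudoscardovia",
                  "Pseudoscardovia", "Pseudoscardovia"),
        stringsAsFactors = FALSE)
}

.defaultVfaTable <- function() {
    data.frame(
        trait = c("propionate", "propionate", "valerate", "valerate"),
        taxon = c("Pseudoscardovia", "p-251-o5",
                  "Pseudoscardovia", "p-251-o5"),
        coef = c(0.8, -0.8, 0.8, -0.8),
        stringsAsFactors = FALSE)
}

setValidity("SynthParams", function(object) {
    tot <- c(object@motherHeritableTotal, object@offspringHeritableTotal,
             object@motherNonheritableTotal,
             object@offspringTrackedNonheritableTotal)
    if (any(tot <= 0 | tot >= 1))
        return("compartment totals must lie in (0, 1)")
    if (object@offspringHeritableTotal +
        object@offspringTrackedNonheritableTotal > 1)
        return("offspring tracked compartments must not exceed 1")
    if (abs(object@motherHeritableTotal +
            object@motherNonheritableTotal - 1) > 1e-8)
        return("mother heritable and nonheritable totals must sum to 1")
    if (object@h2KeyTaxon < 0 || object@h2KeyTaxon > 1)
        return("h2KeyTaxon must lie in [0, 1]")
    if (object@nHeritableFunctions > object@nFunctions)
        return("nHeritableFunctions must not exceed nFunctions")
    if (object@redundancyHeritable <= object@redundancyNonheritable)
        return("redundancyHeritable must exceed redundancyNonheritable")
    if (nrow(object@snpTable) < 5L)
        return("at least 5 SNPs are required")
    if (any(object@snpTable$maf <= 0.05 | object@snpTable$maf >= 0.5))
        return("minor-allele frequencies must lie in (0.05, 0.5)")
    if (any(object@sigmaHeritable < 0, object@sigmaNonheritable < 0))
        return("noise scales must be non-negative")
    TRUE
})

#' Construct synthetic-cohort parameters
#'
#' Any slot of \linkS4class{SynthParams} can be overridden by name; the
#' defaults reproduce the study cohort (see the class documentation).
#'
#' @param ... named slot overrides, e.g. \code{synthParams(nPairs = 20)}.
#' @return A validated \linkS4class{SynthParams}.
#' @examples
#' p <- synthParams()
#' p@nHeritable      # 32
#' @export
synthParams <- function(...) {
    args <- list(
        nMothers = 254, nOffspring = 107, nPairs = 17,
        nHeritable = 32, nNonheritable = 674, nUntracked = 150,
        nFunctions = 236, nHeritableFunctions = 191,
        h2KeyTaxon = 0.79,
        motherHeritableTotal = 0.006, offspringHeritableTotal = 0.007,
        motherNonheritableTotal = 0.994,
        offspringTrackedNonheritableTotal = 0.577,
        targetSimHeritable = 0.94, targetSimNonheritable = 0.85,
        sigmaHeritable = 0.0825, sigmaNonheritable = 0.3932,
        cvMotherHeritableTotal = 0.5, cvOffspringHeritableTotal = 0.75,
        cvTrackedTotal = 0.2,
        baselineSdHeritable = 1.5, baselineSdNonheritable = 2,
        baselineSdUntracked = 2, taxonLogSd = 1,
        redundancyHeritable = 12, redundancyNonheritable = 3,
        snpTable = .defaultSnpTable(), vfaTable = .defaultVfaTable(),
        vfaIntercepts = c(propionate = 25, valerate = 3), vfaNoiseSd = 1,
        seed = 20160301)
    override <- list(...)
    unknown <- setdiff(names(override), names(args))
    if (length(unknown))
        stop(sprintf("unknown parameter(s): %s",
                     paste(unknown, collapse = ", ")))
    args[names(override)] <- override
    do.call(new, c(list("SynthParams"), args))
}

## ---- internal id helpers ---------------------------------------------------

.motherIDs <- function(params)
    sprintf("M%03d", seq_len(params@nMothers))
.offspringIDs <- function(params)
    sprintf("O%03d", seq_len(params@nOffspring))

.cohortTaxa <- function(params) {
    heritable <- if (params@nHeritable == 32) heritableTaxaReference()
                 else sprintf("heritable_%03d", seq_len(params@nHeritable))
    list(heritable = heritable,
         nonheritable = sprintf("nh_%04d", seq_len(params@nNonheritable)),
         untracked = sprintf("untracked_%03d", seq_len(params@nUntracked)))
}

#' Default pair map of a synthetic cohort
#'
#' The first \code{nPairs} mothers are paired with the first \code{nPairs}
#' offspring.
#'
#' @param params a \linkS4class{SynthParams}.
#' @return A \linkS4class{PairMap}.
#' @export
cohortPairMap <- function(params) {
    PairMap(.motherIDs(params)[seq_len(params@nPairs)],
            .offspringIDs(params)[seq_len(params@nPairs)])
}

#' Taxon partition of a synthetic cohort
#'
#' @param params a \linkS4class{SynthParams}.
#' @return A \linkS4class{TaxonPartition} labelling the heritable,
#'   tracked-nonheritable and untracked blocks.
#' @export
cohortPartition <- function(params) {
    tx <- .cohortTaxa(params)
    labels <- c(stats::setNames(rep("heritable", length(tx$heritable)),
                                tx$heritable),
                stats::setNames(rep("nonheritable", length(tx$nonheritable)),
                                tx$nonheritable),
                stats::setNames(rep("untracked", length(tx$untracked)),
                                tx$untracked))
    TaxonPartition(labels)
}

## ---- genotypes -------------------------------------------------------------

#' Simulate two-generation genotypes
#'
#' Mothers are drawn under Hardy-Weinberg equilibrium at each SNP's
#' minor-allele frequency. Each paired offspring inherits one allele drawn
#' uniformly from its mother's pair and one from the population frequency
#' (sires are unobserved); unpaired offspring are drawn under HWE.
#'
#' @param params a \linkS4class{SynthParams}.
#' @param seed integer seed (defaults to \code{params@seed}).
#' @return A \linkS4class{GenotypeTable} covering both generations.
#' @export
simulateGenotypes <- function(params, seed = params@seed) {
    stopifnot(is(params, "SynthParams"))
    .withSeed(seed, {
        snp <- params@snpTable
        mids <- .motherIDs(params); oids <- .offspringIDs(params)
        calls <- matrix(NA_character_,
                        length(mids) + length(oids), nrow(snp),
                        dimnames = list(c(mids, oids), snp$snp))
        for (j in seq_len(nrow(snp))) {
            minor <- snp$effectAllele[j]
            major <- setdiff(c(snp$alleleA[j], snp$alleleB[j]), minor)
            q <- snp$maf[j]
            drawAllele <- function(n)
                ifelse(stats::runif(n) < q, minor, major)
            mA1 <- drawAllele(length(mids)); mA2 <- drawAllele(length(mids))
            oA1 <- character(length(oids)); oA2 <- drawAllele(length(oids))
            paired <- seq_len(params@nPairs)
            fromMother <- ifelse(stats::runif(length(paired)) < 0.5,
                                 mA1[paired], mA2[paired])
            oA1[paired] <- fromMother
            unpaired <- setdiff(seq_along(oids), paired)
            oA1[unpaired] <- drawAllele(length(unpaired))
            calls[, j] <- .sortCall(paste0(c(mA1, oA1), c(mA2, oA2)))
        }
        GenotypeTable(calls)
    })
}

## effect-allele dosage matrix (samples x SNPs) from a GenotypeTable
.dosageMatrix <- function(genotypes, snpTable) {
    cl <- genotypeCalls(genotypes)[, snpTable$snp, drop = FALSE]
    d <- matrix(NA_real_, nrow(cl), ncol(cl), dimnames = dimnames(cl))
    for (j in seq_len(ncol(cl))) {
        al <- snpTable$effectAllele[j]
        d[, j] <- vapply(strsplit(cl[, j], ""),
                         function(p) sum(p == al), 0)
    }
    d
}

## ---- abundances ------------------------------------------------------------

## Per-taxon variance model for the key taxa: total log-scale phenotypic
## variance is taxonLogSd^2 (= 1 by default), split into SNP, polygenic and
## environmental components so that (V_snp + V_poly) / V_P = h2KeyTaxon.
.keyVarComponents <- function(params, taxon) {
    snp <- params@snpTable[params@snpTable$taxon == taxon, , drop = FALSE]
    vSnp <- sum(snp$effectSize^2 * 2 * snp$maf * (1 - snp$maf))
    vP <- params@taxonLogSd^2
    vA <- params@h2KeyTaxon * vP
    if (vSnp > vA)
        warning(sprintf(
            "SNP variance %.3f for '%s' exceeds the additive budget %.3f",
            vSnp, taxon, vA))
    list(vPoly = max(vA - vSnp, 0), vEnv = vP * (1 - params@h2KeyTaxon))
}

## log-abundance matrix for one generation's block of taxa (no totals yet)
.motherBlockLog <- function(params, taxa, mu, dosage = NULL) {
    n <- params@nMothers
    E <- matrix(stats::rnorm(n * length(taxa), 0, params@taxonLogSd),
                n, length(taxa), dimnames = list(.motherIDs(params), taxa))
    L <- sweep(E, 2L, mu, "+")
    if (!is.null(dosage)) {
        for (taxon in unique(params@snpTable$taxon)) {
            if (!taxon %in% taxa) next
            vc <- .keyVarComponents(params, taxon)
            snp <- params@snpTable[params@snpTable$taxon == taxon, ,
                                   drop = FALSE]
            gen <- as.vector(dosage[rownames(L), snp$snp, drop = FALSE] %*%
                             snp$effectSize)
            L[, taxon] <- mu[match(taxon, taxa)] + gen +
                stats::rnorm(n, 0, sqrt(vc$vPoly)) +
                stats::rnorm(n, 0, sqrt(vc$vEnv))
        }
    }
    L
}

## mean-one lognormal jitter
.jitterLN <- function(n, sdlog) exp(stats::rnorm(n, 0, sdlog) - sdlog^2 / 2)

#' Simulate mother and offspring abundance tables
#'
#' Taxon log-abundances are lognormal around per-taxon baselines; the two
#' key taxa additionally carry causal-SNP dosage effects plus a polygenic
#' and an environmental deviate whose variance split is set by
#' \code{h2KeyTaxon}. Each paired offspring's heritable and tracked
#' nonheritable blocks are its mother's blocks under multiplicative
#' lognormal transmission noise (\code{sigmaHeritable} <
#' \code{sigmaNonheritable}, each calibrated against the similarity
#' targets), with the key taxa shifted by the offspring's own dosage;
#' unpaired offspring are fresh population draws. Blocks are rescaled so
#' per-sample compartment totals are mean-one lognormal jitters around the
#' configured totals; an explicit \code{untracked_*} block fills the
#' offspring remainder.
#'
#' @param params a \linkS4class{SynthParams}.
#' @param genotypes a \linkS4class{GenotypeTable} from
#'   \code{\link{simulateGenotypes}}.
#' @param seed integer seed (defaults to \code{params@seed + 1}).
#' @return list with elements \code{mothers} and \code{offspring}
#'   (\linkS4class{AbundanceTable}s) and \code{groundTruth} (list of
#'   baselines, per-sample compartment totals and noise scales).
#' @export
simulateAbundances <- function(params, genotypes, seed = params@seed + 1) {
    stopifnot(is(params, "SynthParams"), is(genotypes, "GenotypeTable"))
    if (params@offspringHeritableTotal +
        params@offspringTrackedNonheritableTotal > 1)
        stop("configured offspring compartment totals exceed 1")
    .withSeed(seed, {
        tx <- .cohortTaxa(params)
        mids <- .motherIDs(params); oids <- .offspringIDs(params)
        nm <- length(mids); no <- length(oids); np <- params@nPairs
        dosage <- .dosageMatrix(genotypes, params@snpTable)

        muH <- stats::rnorm(length(tx$heritable), 0,
                            params@baselineSdHeritable)
        muN <- stats::rnorm(length(tx$nonheritable), 0,
                            params@baselineSdNonheritable)
        muU <- stats::rnorm(length(tx$untracked), 0,
                            params@baselineSdUntracked)

        ## mothers: heritable block carries the genetic architecture
        logHm <- .motherBlockLog(params, tx$heritable, muH, dosage)
        logNm <- .motherBlockLog(params, tx$nonheritable, muN)

        ## offspring: paired rows inherit the mother's block under
        ## multiplicative lognormal noise; key taxa add the dosage delta
        transmit <- function(logM, sigma, taxa, genetic) {
            logO <- matrix(NA_real_, no, ncol(logM),
                           dimnames = list(oids, colnames(logM)))
            logO[seq_len(np), ] <- logM[seq_len(np), , drop = FALSE] +
                stats::rnorm(np * ncol(logM), 0, sigma)
            if (genetic) {
                for (taxon in unique(params@snpTable$taxon)) {
                    if (!taxon %in% colnames(logM)) next
                    snp <- params@snpTable[params@snpTable$taxon == taxon, ,
                                           drop = FALSE]
                    dDos <- dosage[oids[seq_len(np)], snp$snp,
                                   drop = FALSE] -
                            dosage[mids[seq_len(np)], snp$snp, drop = FALSE]
                    logO[seq_len(np), taxon] <-
                        logO[seq_len(np), taxon] +
                        as.vector(dDos %*% snp$effectSize)
                }
            }
            logO
        }
        logHo <- transmit(logHm, params@sigmaHeritable, tx$heritable, TRUE)
        logNo <- transmit(logNm, params@sigmaNonheritable,
                          tx$nonheritable, FALSE)

        ## unpaired offspring: fresh population draws with own genotypes
        if (no > np) {
            un <- (np + 1L):no
            freshH <- .freshBlockLog(params, oids[un], tx$heritable, muH,
                                     dosage)
            freshN <- .freshBlockLog(params, oids[un], tx$nonheritable, muN,
                                     NULL)
            logHo[un, ] <- freshH
            logNo[un, ] <- freshN
        }
        logUo <- .freshBlockLog(params, oids, tx$untracked, muU, NULL)

        ## per-sample compartment totals: mean-one lognormal jitter around
        ## the configured means; offspring tracked total capped so the
        ## untracked remainder stays positive
        thM <- params@motherHeritableTotal *
            .jitterLN(nm, params@cvMotherHeritableTotal)
        thO <- params@offspringHeritableTotal *
            .jitterLN(no, params@cvOffspringHeritableTotal)
        tnO <- params@offspringTrackedNonheritableTotal *
            .jitterLN(no, params@cvTrackedTotal)
        over <- thO + tnO > 0.99
        tnO[over] <- 0.99 - thO[over]

        compose <- function(logBlocks, totals) {
            blocks <- Map(function(L, tot) {
                W <- exp(L)
                W / rowSums(W) * tot
            }, logBlocks, totals)
            m <- do.call(cbind, blocks)
            AbundanceTable(m / rowSums(m))
        }
        mothers <- compose(list(logHm, logNm), list(thM, 1 - thM))
        offspring <- compose(list(logHo, logNo, logUo),
                             list(thO, tnO, 1 - thO - tnO))

        list(mothers = mothers, offspring = offspring,
             groundTruth = list(
                 muHeritable = stats::setNames(muH, tx$heritable),
                 muNonheritable = stats::setNames(muN, tx$nonheritable),
                 muUntracked = stats::setNames(muU, tx$untracked),
                 motherHeritableTotals = stats::setNames(thM, mids),
                 offspringHeritableTotals = stats::setNames(thO, oids),
                 offspringTrackedTotals = stats::setNames(tnO, oids),
                 dosage = dosage,
                 sigmaHeritable = params@sigmaHeritable,
                 sigmaNonheritable = params@sigmaNonheritable,
                 keyTaxa = unique(params@snpTable$taxon)))
    })
}

.freshBlockLog <- function(params, ids, taxa, mu, dosage) {
    L <- matrix(stats::rnorm(length(ids) * length(taxa), 0,
                             params@taxonLogSd),
                length(ids), length(taxa), dimnames = list(ids, taxa))
    L <- sweep(L, 2L, mu, "+")
    if (!is.null(dosage)) {
        for (taxon in unique(params@snpTable$taxon)) {
            if (!taxon %in% taxa) next
            vc <- .keyVarComponents(params, taxon)
            snp <- params@snpTable[params@snpTable$taxon == taxon, ,
                                   drop = FALSE]
            gen <- as.vector(dosage[ids, snp$snp, drop = FALSE] %*%
                             snp$effectSize)
            L[, taxon] <- mu[match(taxon, taxa)] + gen +
                stats::rnorm(length(ids), 0, sqrt(vc$vPoly)) +
                stats::rnorm(length(ids), 0, sqrt(vc$vEnv))
        }
    }
    L
}

## ---- functions -------------------------------------------------------------

#' Simulate a taxon-by-function gene-content matrix
#'
#' Heritable taxa draw gene content from a shared pool of
#' \code{nHeritableFunctions} functions with high overlap (on average
#' \code{redundancyHeritable} heritable taxa per pool function, every pool
#' function touched by at least one heritable taxon); nonheritable taxa
#' draw sparser, less-overlapping content across all \code{nFunctions}
#' functions. This redundancy asymmetry is the generative mechanism behind
#' the heritable block's higher taxa-function stability.
#'
#' @param params a \linkS4class{SynthParams}.
#' @param partition a \linkS4class{TaxonPartition} (defaults to
#'   \code{cohortPartition(params)}).
#' @param seed integer seed (defaults to \code{params@seed + 2}).
#' @return A \linkS4class{FunctionContentMatrix} over the heritable and
#'   nonheritable taxa.
#' @export
simulateFunctions <- function(params, partition = cohortPartition(params),
                              seed = params@seed + 2) {
    stopifnot(is(params, "SynthParams"), is(partition, "TaxonPartition"))
    .withSeed(seed, {
        her <- taxaByLabel(partition, "heritable")
        non <- taxaByLabel(partition, "nonheritable")
        fun <- sprintf("F%03d", seq_len(params@nFunctions))
        nhf <- params@nHeritableFunctions
        G <- matrix(0, length(her) + length(non), params@nFunctions,
                    dimnames = list(c(her, non), fun))

        ## heritable block: only the first nhf columns, >= 1 taxon each
        pH <- min((params@redundancyHeritable - 1) /
                  max(length(her) - 1, 1), 1)
        for (j in seq_len(nhf)) {
            k <- 1L + stats::rbinom(1L, length(her) - 1L, pH)
            members <- sample(her, k)
            G[members, j] <- stats::rlnorm(k, 0, 0.5)
        }
        ## nonheritable block: all columns, sparse membership; columns
        ## beyond the heritable pool keep >= 1 member so no function
        ## column is all-zero
        pN <- min(params@redundancyNonheritable / length(non), 1)
        for (j in seq_len(params@nFunctions)) {
            k <- stats::rbinom(1L, length(non), pN)
            if (j > nhf) k <- max(k, 1L)
            if (k == 0L) next
            members <- sample(non, k)
            G[members, j] <- stats::rlnorm(k, 0, 0.5)
        }
        ## every analyzed taxon touches at least one function
        orphan <- rownames(G)[rowSums(G) == 0]
        for (tax in orphan) {
            j <- if (tax %in% her) sample(nhf, 1L)
                 else sample(params@nFunctions, 1L)
            G[tax, j] <- stats::rlnorm(1L, 0, 0.5)
        }
        FunctionContentMatrix(G)
    })
}

## ---- phenotypes ------------------------------------------------------------

#' Simulate volatile fatty acid phenotypes
#'
#' Each VFA trait is a linear function of the log relative abundances of
#' the key taxa in the mother table plus Gaussian noise; the default
#' coefficients make propionate and valerate rise with Pseudoscardovia and
#' fall with p-251-o5.
#'
#' @param params a \linkS4class{SynthParams}.
#' @param motherTable the mother \linkS4class{AbundanceTable}.
#' @param seed integer seed (defaults to \code{params@seed + 3}).
#' @return A \linkS4class{PhenotypeTable}.
#' @export
simulateVFA <- function(params, motherTable, seed = params@seed + 3) {
    stopifnot(is(params, "SynthParams"), is(motherTable, "AbundanceTable"))
    need <- unique(params@vfaTable$taxon)
    missing <- setdiff(need, taxonIDs(motherTable))
    if (length(missing))
        stop(sprintf("key taxa absent from the mother table: %s",
                     paste(missing, collapse = ", ")))
    .withSeed(seed, {
        ab <- abundances(motherTable)
        traits <- unique(params@vfaTable$trait)
        out <- matrix(NA_real_, nrow(ab), length(traits),
                      dimnames = list(rownames(ab), traits))
        for (tr in traits) {
            rows <- params@vfaTable[params@vfaTable$trait == tr, ,
                                    drop = FALSE]
            v <- rep(params@vfaIntercepts[[tr]], nrow(ab))
            for (i in seq_len(nrow(rows)))
                v <- v + rows$coef[i] * log(ab[, rows$taxon[i]])
            out[, tr] <- v + stats::rnorm(nrow(ab), 0, params@vfaNoiseSd)
        }
        PhenotypeTable(out)
    })
}

## ---- calibration -----------------------------------------------------------

#' Calibrate a transmission-noise scale against a similarity target
#'
#' Finds the noise scale sigma for which the Monte-Carlo mean
#' mother-offspring similarity (1 - Bray-Curtis on the labelled subset,
#' renormalized) matches \code{target}, by bisection on
#' \code{[0, sigmaMax]}. Mean similarity is monotone decreasing in sigma;
#' the estimate at each candidate uses at least \code{nPairsMC} simulated
#' pairs on a fixed seed schedule, generated with the full cohort
#' machinery (pairs-only cohorts).
#'
#' @param params a \linkS4class{SynthParams}; all settings except the
#'   calibrated sigma are taken from it.
#' @param label \code{"heritable"} (calibrates \code{sigmaHeritable}) or
#'   \code{"nonheritable"} (calibrates \code{sigmaNonheritable}).
#' @param target desired mean similarity in (0, 1); defaults to the
#'   corresponding \code{targetSim*} parameter.
#' @param tol absolute tolerance on the achieved mean similarity.
#' @param seed integer seed for the Monte-Carlo seed schedule.
#' @param nPairsMC minimum number of simulated pairs per evaluation.
#' @param sigmaMax upper end of the bisection bracket.
#' @return the calibrated sigma (numeric scalar).
#' @export
calibrateSimilarity <- function(params, label = c("heritable",
                                                  "nonheritable"),
                                target = NULL, tol = 0.005,
                                seed = params@seed, nPairsMC = 340,
                                sigmaMax = 3) {
    stopifnot(is(params, "SynthParams"))
    label <- match.arg(label)
    if (is.null(target))
        target <- if (label == "heritable") params@targetSimHeritable
                  else params@targetSimNonheritable
    if (target <= 0 || target >= 1 + 1e-12)
        stop("target similarity must lie in (0, 1]")

    nChunks <- ceiling(nPairsMC / params@nPairs)
    seeds <- .childSeeds(seed, nChunks)
    meanSim <- function(sigma) {
        sims <- unlist(lapply(seeds, function(s) {
            p <- params
            if (label == "heritable") p@sigmaHeritable <- sigma
            else p@sigmaNonheritable <- sigma
            p@nMothers <- p@nPairs
            p@nOffspring <- p@nPairs
            gt <- simulateGenotypes(p, seed = s)
            ab <- simulateAbundances(p, gt, seed = s + 1)
            recs <- pairwiseSimilarity(ab$mothers, ab$offspring,
                                       cohortPairMap(p),
                                       cohortPartition(p), label)
            recs$similarity
        }))
        mean(sims)
    }
    hi <- meanSim(0)
    lo <- meanSim(sigmaMax)
    if (target >= hi) {
        if (target - hi <= tol) return(0)
        stop(sprintf(
            "target %.4f unreachable: attainable range is [%.4f, %.4f]",
            target, lo, hi))
    }
    if (target < lo)
        stop(sprintf(
            "target %.4f unreachable: attainable range is [%.4f, %.4f]",
            target, lo, hi))
    a <- 0; b <- sigmaMax
    for (i in seq_len(40L)) {
        mid <- (a + b) / 2
        m <- meanSim(mid)
        if (abs(m - target) <= tol / 2) return(mid)
        if (m > target) a <- mid else b <- mid
        if (b - a < 1e-4) break
    }
    (a + b) / 2
}

## ---- cohort bundle ---------------------------------------------------------

#' Simulate a complete paired cohort
#'
#' Runs genotype, abundance, gene-content and phenotype simulation with
#' seeds derived from one master seed and bundles the results with the
#' pair map, partition and ground truth.
#'
#' @param params a \linkS4class{SynthParams}.
#' @param seed master integer seed (defaults to \code{params@seed}).
#' @return A \linkS4class{SynthCohort}.
#' @examples
#' co <- simulateCohort(synthParams(nMothers = 20, nOffspring = 20,
#'                                  nPairs = 5, nNonheritable = 50,
#'                                  nUntracked = 10), seed = 1)
#' co
#' @export
simulateCohort <- function(params = synthParams(), seed = params@seed) {
    stopifnot(is(params, "SynthParams"))
    seeds <- .childSeeds(seed, 4L)
    genotypes <- simulateGenotypes(params, seed = seeds[1L])
    ab <- simulateAbundances(params, genotypes, seed = seeds[2L])
    partition <- cohortPartition(params)
    functions <- simulateFunctions(params, partition, seed = seeds[3L])
    phenotypes <- simulateVFA(params, ab$mothers, seed = seeds[4L])
    new("SynthCohort", mothers = ab$mothers, offspring = ab$offspring,
        genotypes = genotypes, pairs = cohortPairMap(params),
        partition = partition, functions = functions,
        phenotypes = phenotypes,
        groundTruth = c(ab$groundTruth, list(masterSeed = seed)),
        params = params)
}

#' Simulate parent-offspring phenotype pairs under the additive model
#'
#' Validation harness for the heritability machinery: parent phenotype is
#' additive value plus environment (total variance 1, additive fraction
#' \code{h2}); the offspring additive value is half the parent's plus a
#' Mendelian-sampling deviate of variance \code{0.75 * h2} (random mate),
#' giving the textbook parent-offspring covariance \code{h2 / 2}.
#'
#' @param nPairs number of pairs.
#' @param h2 narrow-sense heritability in [0, 1].
#' @param seed integer seed.
#' @return data.frame with columns \code{parent} and \code{offspring}.
#' @export
simulateParentOffspringPairs <- function(nPairs, h2, seed) {
    stopifnot(nPairs >= 2, h2 >= 0, h2 <= 1)
    .withSeed(seed, {
        aP <- stats::rnorm(nPairs, 0, sqrt(h2))
        parent <- aP + stats::rnorm(nPairs, 0, sqrt(1 - h2))
        aO <- 0.5 * aP + stats::rnorm(nPairs, 0, sqrt(0.75 * h2))
        offspring <- aO + stats::rnorm(nPairs, 0, sqrt(1 - h2))
        data.frame(parent = parent, offspring = offspring)
    })
}
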