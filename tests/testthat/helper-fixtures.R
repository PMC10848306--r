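## Fixture builders; everything is generated in code at test time.

## Reduced cohort for fast end-to-end tests (heritable panel stays at the
## 32 reference taxa so the causal-SNP machinery is exercised).
smallParams <- function(...) {
    synthParams(nMothers = 30, nOffspring = 24, nPairs = 8,
                nNonheritable = 80, nUntracked = 25,
                nFunctions = 60, nHeritableFunctions = 45,
                redundancyHeritable = 8, redundancyNonheritable = 2, ...)
}

## A tiny hand-built abundance table.
tinyAbundance <- function(values = c(0.5, 0.5, 0.2, 0.8),
                          samples = c("s1", "s2"),
                          taxa = c("t1", "t2")) {
    AbundanceTable(matrix(values, nrow = length(samples), byrow = TRUE,
                          dimnames = list(samples, taxa)))
}

## Random compositions for property-style loops.
randomComposition <- function(n) {
    x <- rexp(n)
    x / sum(x)
}

## One small simulated cohort, memoised across tests in a file.
localCohort <- local({
    cache <- new.env(parent = emptyenv())
    function(seed = 42) {
        key <- as.character(seed)
        if (is.null(cache[[key]]))
            cache[[key]] <- simulateCohort(smallParams(), seed = seed)
        cache[[key]]
    }
})
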