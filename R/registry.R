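#' Reference registry of heritable rumen bacteria
#'
#' The packaged list of the 32 species-level rumen bacterial taxa reported
#' as significantly heritable in Holstein dairy cows. Names that repeat in
#' the published list (e.g. Izemoplasmatales, Roseburia) are disambiguated
#' by order of appearance with \code{"_1"} suffixes, following the same
#' convention the source list uses.
#'
#' @return character vector of 32 disambiguated taxon ids, in the published
#'   order.
#' @examples
#' length(heritableTaxaReference())  # 32
#' @export
heritableTaxaReference <- function() {
    path <- system.file("extdata", "heritable_taxa.tsv",
                        package = "rumenTransmit", mustWork = TRUE)
    df <- .readTSV(path)
    ids <- df$taxon_id
    stopifnot(!anyDuplicated(ids))
    ids
}

## Key heritable taxa whose abundance the study links to host genotype and
## rumen VFAs: Pseudoscardovia (positively associated with propionate and
## valerate) and p-251-o5 (negatively associated).
.keyTaxa <- c("Pseudoscardovia", "p-251-o5")
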