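## Internal helpers shared across modules.

## Run `expr` under a local RNG state seeded with `seed`; the caller's
## .Random.seed is restored on exit so simulations never perturb user code.
.withSeed <- function(seed, expr) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

## Derive a stream of child seeds from one master seed, kept inside the
## 32-bit integer range.
.childSeeds <- function(seed, n) {
    (as.integer(seed) + 77777L * seq_len(n)) %% 2147483587L
}

## Disambiguate duplicated identifiers by order of appearance: the first
## occurrence keeps the base name, later ones get "_1", "_2", ... (the
## convention used for repeated taxon names such as "Izemoplasmatales_1").
.disambiguate <- function(ids) {
    ids <- as.character(ids)
    counts <- new.env(parent = emptyenv())
    vapply(ids, function(id) {
        k <- if (is.null(counts[[id]])) 0L else counts[[id]]
        counts[[id]] <- k + 1L
        if (k == 0L) id else paste0(id, "_", k)
    }, "", USE.NAMES = FALSE)
}

## TSV I/O used by every reader/writer: tab-delimited, UTF-8, '#' comments
## ignored, no name mangling.
.readTSV <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      quote = "", row.names = NULL)
}

.writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
}

## Full-precision numeric formatting so write/read round-trips to 1e-12.
.formatNum <- function(x) formatC(x, digits = 17, format = "g")

.matrixToFrame <- function(m, idCol) {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c(idCol, colnames(m))
    df
}

.frameToMatrix <- function(df) {
    ids <- .disambiguate(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) storage.mode(m) <- "double"
    rownames(m) <- ids
    colnames(m) <- .disambiguate(names(df)[-1L])
    m
}
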