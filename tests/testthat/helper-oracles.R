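## Hand-formula reference implementations, kept independent of the code
## paths they check.

## Kruskal-Wallis H from the rank-sum formula with tie correction.
oracleKW <- function(groups) {
    x <- unlist(groups)
    n <- length(x)
    r <- rank(x)
    splits <- split(r, rep(seq_along(groups), lengths(groups)))
    H <- 12 / (n * (n + 1)) *
        sum(vapply(splits, function(ri) sum(ri)^2 / length(ri), 0)) -
        3 * (n + 1)
    ties <- table(x)
    H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

## Benjamini-Hochberg step-up, from the definition.
oracleBH <- function(p) {
    m <- length(p)
    ord <- order(p, decreasing = TRUE)
    adj <- numeric(m)
    running <- Inf
    for (i in seq_len(m)) {
        k <- ord[i]
        rankK <- m - i + 1L
        running <- min(running, p[k] * m / rankK)
        adj[k] <- min(running, 1)
    }
    adj
}

## Spearman rho as the Pearson correlation of the rank vectors, written out.
oracleSpearman <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    dx <- rx - mean(rx); dy <- ry - mean(ry)
    sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

## Welch t statistic, Welch-Satterthwaite df and two-sided P.
oracleWelch <- function(a, b) {
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## Paired t as a one-sample t on the differences.
oraclePaired <- function(a, b) {
    d <- a - b
    t <- mean(d) / (sd(d) / sqrt(length(d)))
    list(t = t, df = length(d) - 1, p = 2 * pt(-abs(t), length(d) - 1))
}

## Bray-Curtis via vegan (the package the similarity analysis mirrors).
oracleBray <- function(x, y) {
    as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}
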