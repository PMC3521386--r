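# Loop-based oracles, independent of the vectorized implementations.

oracleStats <- function(m, rows, cols) {
    rowMeans <- vapply(rows, function(i) {
        s <- 0
        for (j in cols) s <- s + m[i, j]
        s / length(cols)
    }, numeric(1))
    colMeans <- vapply(cols, function(j) {
        s <- 0
        for (i in rows) s <- s + m[i, j]
        s / length(rows)
    }, numeric(1))
    grand <- 0
    for (i in rows) for (j in cols) grand <- grand + m[i, j]
    grand <- grand / (length(rows) * length(cols))
    H <- 0
    V <- 0
    for (a in seq_along(rows)) for (b in seq_along(cols)) {
        e <- m[rows[a], cols[b]]
        h <- e - rowMeans[a] - colMeans[b] + grand
        H <- H + h * h
        d <- e - rowMeans[a]
        V <- V + d * d
    }
    list(rowMeans = rowMeans, colMeans = colMeans, grandMean = grand,
         H = H / (length(rows) * length(cols)),
         V = V / (length(rows) * length(cols)))
}

# Exhaustive enumeration of every >= 2x2 submatrix score.
oracleExhaustiveBest <- function(m, params) {
    N <- nrow(m); M <- ncol(m)
    rowSets <- unlist(lapply(2:N, function(k) combn(N, k, simplify = FALSE)),
                      recursive = FALSE)
    colSets <- unlist(lapply(2:M, function(k) combn(M, k, simplify = FALSE)),
                      recursive = FALSE)
    best <- Inf; arg <- NULL
    for (rs in rowSets) for (cs in colSets) {
        sc <- biclusterScore(scoreBicluster(m, rs, cs, params))
        if (sc < best) { best <- sc; arg <- list(rows = rs, cols = cs) }
    }
    list(score = best, rows = arg$rows, cols = arg$cols)
}

# Tiny matrix with a planted additive 3x3 block in rows/cols 1:3.
plantedTinyMatrix <- function(seed, nRows = 8, nCols = 6) {
    m <- generateBackground(nRows, nCols, 0, 500, seed = seed)
    a <- c(0, 30, 60); b <- c(100, 250, 400)
    m[1:3, 1:3] <- outer(a, b, "+")
    m
}
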