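test_that("submatrix means match hand arithmetic and the loop oracle", {
    m <- matrix(c(1, 2, 3, 4), nrow = 2, byrow = TRUE)
    s <- submatrixMeans(m, 1:2, 1:2)
    expect_equal(s$rowMeans, c(1.5, 3.5), ignore_attr = TRUE)
    expect_equal(s$colMeans, c(2, 3), ignore_attr = TRUE)
    expect_equal(s$grandMean, 2.5)

    const <- matrix(7, 4, 3)
    s <- submatrixMeans(const, 1:4, 1:3)
    expect_true(all(s$rowMeans == 7) && all(s$colMeans == 7) &&
                s$grandMean == 7)

    m <- generateBackground(8, 6, 0, 500, seed = 42)
    rows <- c(2, 3, 5, 7, 8); cols <- c(1, 3, 4, 6)
    s <- submatrixMeans(m, rows, cols)
    o <- oracleStats(m, rows, cols)
    expect_equal(s$rowMeans, o$rowMeans, ignore_attr = TRUE)
    expect_equal(s$colMeans, o$colMeans, ignore_attr = TRUE)
    expect_equal(s$grandMean, o$grandMean)

    expect_error(submatrixMeans(m, integer(0), cols), "at least")
    expect_error(submatrixMeans(m, c(1, 99), cols), "out of bounds")
})

test_that("mean squared residue is zero for additive models and matches the oracle", {
    expect_equal(meanSquaredResidue(matrix(5, 3, 4), 1:3, 1:4), 0)

    additive <- outer(c(3, 17, -2, 40), c(0, 100, 7), "+")
    expect_equal(meanSquaredResidue(additive, 1:4, 1:3), 0)

    m <- generateBackground(8, 6, 0, 500, seed = 7)
    expect_equal(meanSquaredResidue(m, 4, 1:6), 0)  # single row
    expect_equal(meanSquaredResidue(m, 1:8, 3), 0)  # single column

    for (seed in 1:5) {
        m <- generateBackground(7, 6, 0, 500, seed = seed)
        rows <- sort(sample(7, 6)); cols <- sort(sample(6, 5))
        o <- oracleStats(m, rows, cols)
        expect_equal(meanSquaredResidue(m, rows, cols), o$H,
                     tolerance = 1e-9)
    }
})

test_that("residue is invariant to shifting a full row or column of the submatrix", {
    m <- generateBackground(10, 8, 0, 500, seed = 3)
    rows <- 2:7; cols <- c(1, 4, 5, 8)
    H0 <- meanSquaredResidue(m, rows, cols)
    m2 <- m; m2[4, cols] <- m2[4, cols] + 123.4
    expect_equal(meanSquaredResidue(m2, rows, cols), H0, tolerance = 1e-9)
    m3 <- m; m3[rows, 5] <- m3[rows, 5] - 77.7
    expect_equal(meanSquaredResidue(m3, rows, cols), H0, tolerance = 1e-9)
})

test_that("row variance detects flat rows and matches the oracle", {
    flat <- matrix(rep(c(1, 5, 9), each = 4), nrow = 3, byrow = TRUE)
    expect_equal(rowVariance(flat, 1:3, 1:4), 0)

    m12 <- matrix(c(0, 2), nrow = 1)
    expect_equal(rowVariance(m12, 1, 1:2), 1)

    for (seed in 1:5) {
        m <- generateBackground(7, 6, 0, 500, seed = 10 + seed)
        rows <- sort(sample(7, 5)); cols <- sort(sample(6, 4))
        o <- oracleStats(m, rows, cols)
        expect_equal(rowVariance(m, rows, cols), o$V, tolerance = 1e-9)
    }
})

test_that("score terms follow their piecewise/limit definitions", {
    expect_equal(residueTerm(40, 20), 2)
    expect_equal(residueTerm(0, 20), 1)
    expect_equal(residueTerm(20, 20), 1)  # boundary belongs to else-branch
    expect_equal(residueTerm(20 + 1e-9, 20), (20 + 1e-9) / 20)

    expect_equal(varianceTerm(0.5, 0.5), 1)
    expect_lt(varianceTerm(1e12, 0.5), 1e-9)
    expect_equal(varianceTerm(0, 0.5), 1e6)
    expect_true(varianceTerm(2, 0.5) < varianceTerm(1, 0.5))

    p <- scoreParams("artificial")
    expect_equal(volumeTerm(12, 9, 100, 20, p), 10 * (0.9 / 12 + 0.1 / 9))
    expect_lt(volumeTerm(16, 9, 100, 20, p), volumeTerm(12, 9, 100, 20, p))
    lit <- scoreParams("artificial", volumeForm = "literal_fraction")
    expect_equal(volumeTerm(16, 9, 100, 20, lit),
                 10 * (0.9 * 16 / 100 + 0.1 * 9 / 20))
})

test_that("bicluster score composes the three terms and is order-invariant", {
    d <- generatePreset("Ea", seed = 5)
    m <- exprMatrix(d)
    p <- scoreParams("artificial")
    rows <- c(9, 2, 55, 31); cols <- c(14, 3, 8)
    b <- scoreBicluster(m, rows, cols, p)
    H <- meanSquaredResidue(m, rows, cols)
    V <- rowVariance(m, rows, cols)
    expect_equal(residueScore(b), H)
    expect_equal(varianceScore(b), V)
    expect_equal(biclusterVolume(b), 12)
    expect_equal(biclusterScore(b),
                 residueTerm(H, p@delta) + varianceTerm(V, 0.5) +
                 volumeTerm(4, 3, 100, 20, p))

    b2 <- scoreBicluster(m, rev(rows), rev(cols), p)
    expect_equal(biclusterScore(b2), biclusterScore(b))
    expect_equal(geneIndices(b2), geneIndices(b))

    tb <- truthBlocks(d)[[1]]
    planted <- scoreBicluster(m, tb$rows, tb$cols, p)
    expect_equal(residueTerm(residueScore(planted), p@delta), 1)

    expect_error(scoreBicluster(m, 5, 1:4, p), "at least")
})

test_that("score parameters serialize to the published field names and back", {
    p <- scoreParams("real", wV = 25)
    l <- scoreParamsToList(p)
    expect_named(l, c("delta", "w_b", "w_v", "w_g", "w_c", "volume_form"))
    expect_equal(l$delta, 250)
    expect_equal(l$w_v, 25)
    p2 <- scoreParamsFromList(l)
    expect_equal(p2, p, ignore_attr = TRUE)
    expect_error(scoreParamsFromList(list(delta = 20, bogus = 1)), "unknown")
    expect_error(scoreParams(delta = -1))
})
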