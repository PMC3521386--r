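writeTsv <- function(lines) {
    tf <- tempfile(fileext = ".tsv")
    writeLines(lines, tf)
    tf
}

test_that("expression matrix TSV parsing handles labels, missing tokens and errors", {
    tf <- writeTsv(c("gene\tc1\tc2", "g1\t1\t2", "g2\t3\t4", "g3\t5\t6"))
    m <- readExpressionMatrix(tf)
    expect_equal(dim(m), c(3L, 2L))
    expect_equal(rownames(m), c("g1", "g2", "g3"))
    expect_equal(colnames(m), c("c1", "c2"))
    expect_equal(sum(is.na(m)), 0L)
    expect_equal(m["g2", "c2"], 4)

    tf <- writeTsv(c("gene\tc1\tc2", "g1\t1\tNA", "g2\t3\t4"))
    m <- readExpressionMatrix(tf)
    expect_equal(sum(is.na(m)), 1L)
    expect_true(is.na(m["g1", "c2"]))

    # case-insensitive default tokens; custom token set replaces them
    tf <- writeTsv(c("gene\tc1\tc2", "g1\t1\tNULL", "g2\t3\t4"))
    expect_equal(sum(is.na(readExpressionMatrix(tf))), 1L)
    tf <- writeTsv(c("gene\tc1\tc2", "g1\t1\t-9", "g2\t-9\t4"))
    expect_equal(sum(is.na(readExpressionMatrix(tf))), 0L)
    expect_equal(sum(is.na(readExpressionMatrix(tf, missingTokens = "-9"))),
                 2L)

    tf <- writeTsv(c("gene\tc1\tc2", "g1\t1", "g2\t3\t4"))
    expect_error(readExpressionMatrix(tf), "row 2")

    tf <- writeTsv(c("gene\tc1\tc2", "g1\t1\t2", "g1\t3\t4"))
    expect_error(readExpressionMatrix(tf), "duplicate gene")

    tf <- writeTsv(c("gene\tc1\tc1", "g1\t1\t2", "g2\t3\t4"))
    expect_error(readExpressionMatrix(tf), "duplicate condition")

    tf <- writeTsv(c("gene\tc1\tc2", "g1\t1\tabc", "g2\t3\t4"))
    expect_error(readExpressionMatrix(tf), "non-numeric")
})

test_that("expression matrices round-trip through write and read", {
    m <- generateBackground(5, 4, 0, 500, seed = 1)
    m[2, 3] <- NA
    tf <- tempfile(fileext = ".tsv")
    writeExpressionMatrix(m, tf)
    m2 <- readExpressionMatrix(tf)
    expect_equal(m2, m, tolerance = 1e-12)
})

test_that("uniform imputation touches exactly the missing entries, reproducibly", {
    m <- generateBackground(10, 6, 0, 500, seed = 2)
    expect_identical(imputeMissingUniform(m, 0, 600, seed = 1), m)

    miss <- cbind(c(1, 4, 7, 9, 10), c(2, 5, 1, 6, 3))
    m[miss] <- NA
    imp <- imputeMissingUniform(m, 0, 600, seed = 9)
    expect_false(anyNA(imp))
    expect_true(all(imp[miss] >= 0 & imp[miss] <= 600))
    untouched <- !is.na(m)
    expect_identical(imp[untouched], m[untouched])

    expect_identical(imputeMissingUniform(m, 0, 600, seed = 9), imp)
    expect_false(identical(imputeMissingUniform(m, 0, 600, seed = 10), imp))
    expect_error(imputeMissingUniform(m, 10, 5, seed = 1))
})

test_that("bicluster reports round-trip and use labels, never indices", {
    d <- generatePreset("Ea", seed = 3)
    m <- exprMatrix(d)
    p <- scoreParams("artificial")
    bcs <- list(scoreBicluster(m, c(3, 10), c(2, 5), p),
                scoreBicluster(m, 20:25, c(1, 4, 9, 11), p))
    tf <- tempfile(fileext = ".tsv")
    writeBiclusterResults(bcs, m, tf)

    lines <- readLines(tf)
    expect_length(lines, 3L)
    expect_match(lines[2], "g3,g10")
    expect_match(lines[2], "c2,c5")

    back <- readBiclusterResults(tf, m)
    expect_length(back, 2L)
    for (k in 1:2) {
        expect_equal(geneIndices(back[[k]]), geneIndices(bcs[[k]]))
        expect_equal(conditionIndices(back[[k]]), conditionIndices(bcs[[k]]))
        expect_equal(biclusterScore(back[[k]]), biclusterScore(bcs[[k]]),
                     tolerance = 1e-12)
    }

    tf2 <- tempfile(fileext = ".tsv")
    writeBiclusterResults(list(), m, tf2)
    expect_length(readLines(tf2), 1L)  # header only
    expect_length(readBiclusterResults(tf2, m), 0L)

    bad <- new("Bicluster", rows = c(1L, 999L), cols = c(1L, 2L),
               H = 0, V = 1, volume = 4, score = 1)
    expect_error(writeBiclusterResults(list(bad), m, tempfile()), "bounds")
})
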