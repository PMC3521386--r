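test_that("budget-matched comparisons are deterministic and evenly budgeted", {
    d <- generatePreset("Ea", seed = 1)
    s1 <- runComparison(d, c("PCOBA", "GA"), nRuns = 2, budget = 1500,
                        baseSeed = 7)
    s2 <- runComparison(d, c("PCOBA", "GA"), nRuns = 2, budget = 1500,
                        baseSeed = 7)
    expect_equal(s1, s2, ignore_attr = TRUE)
    expect_identical(attr(s1, "runs"), attr(s2, "runs"))

    runs <- attr(s1, "runs")
    expect_equal(nrow(runs), 4L)
    # every run stopped within one generation's worth of the budget;
    # the largest generation here costs max(R*nu, popSize) evaluations
    perGenMax <- max(5 * 50 + 100, 100)
    expect_true(all(runs$nEvaluations >= 1500))
    expect_true(all(runs$nEvaluations <= 1500 + perGenMax))
    expect_lt(max(s1$evalsMean) - min(s1$evalsMean), perGenMax)

    # summary statistics equal a direct recomputation from per-run records
    sub <- runs[runs$algorithm == "PCOBA", ]
    expect_equal(s1$residueMean[s1$algorithm == "PCOBA"], mean(sub$residue))
    expect_equal(s1$residueSd[s1$algorithm == "PCOBA"], sd(sub$residue))
    expect_equal(s1$fitnessSd[s1$algorithm == "PCOBA"], sd(sub$fitness))
    expect_true(all(!is.na(runs$recovery)))

    expect_error(runComparison(d, "PCOBA", nRuns = 1, budget = 100),
                 "budget")
})

test_that("comparison summaries can be written as a table", {
    d <- generatePreset("Ea", seed = 2)
    tf <- tempfile(fileext = ".tsv")
    s <- runComparison(d, "PCOBA", nRuns = 1, budget = 600, baseSeed = 1,
                       out = tf)
    tab <- read.delim(tf)
    expect_equal(nrow(tab), 1L)
    expect_equal(tab$algorithm, "PCOBA")
    expect_equal(tab$residueMean, s$residueMean)
})

test_that("trajectory reports enforce monotone fitness and round-trip as TSV", {
    m <- plantedTinyMatrix(seed = 30)
    run <- runPcoba(m, pcobaConfig("artificial", mu = 20L, nu = 10L,
                                   maxGen = 25L, Sg = 4L, Sc = 2L, R = 2L,
                                   seed = 1L))
    tf <- tempfile(fileext = ".tsv")
    trajectoryReport(run, tf)
    tab <- read.delim(tf)
    expect_equal(nrow(tab), 25L)
    expect_equal(names(tab), c("generation", "fitness", "H", "V", "volume"))
    expect_true(all(diff(tab$fitness) <= 1e-12))

    bad <- data.frame(generation = 1:3, fitness = c(3, 1, 2),
                      H = 0, V = 1, volume = 4)
    expect_error(trajectoryReport(bad, tempfile()), "non-increasing")
})

test_that("averaged trajectories over seeds retain monotone mean fitness", {
    m <- plantedTinyMatrix(seed = 31)
    runs <- lapply(1:5, function(s)
        runPcoba(m, pcobaConfig("artificial", mu = 20L, nu = 10L,
                                maxGen = 20L, Sg = 4L, Sc = 2L, R = 2L,
                                seed = s)))
    avg <- averageTrajectories(runs)
    expect_equal(nrow(avg), 20L)
    expect_true(all(diff(avg$fitness) <= 1e-12))
})

test_that("top-bicluster extraction deduplicates and caps pairwise overlap", {
    mk <- function(rows, cols, score) new("Bicluster", rows = as.integer(rows),
        cols = as.integer(cols), H = 1, V = 1,
        volume = length(rows) * length(cols), score = score)
    one <- topBiclusters(list(mk(1:3, 1:3, 2)), k = 10)
    expect_length(one, 1L)

    dup <- topBiclusters(list(mk(1:3, 1:3, 2), mk(1:3, 1:3, 2.1)), k = 10)
    expect_length(dup, 1L)
    expect_equal(biclusterScore(dup[[1]]), 2)

    cands <- list(mk(1:4, 1:4, 1), mk(1:4, 1:5, 1.5),  # Jaccard 0.8 with first
                  mk(10:13, 1:4, 2), mk(20:21, 8:9, 3))
    kept <- topBiclusters(cands, k = 10, maxOverlap = 0.25)
    scores <- vapply(kept, biclusterScore, numeric(1))
    expect_equal(scores, sort(scores))
    for (a in seq_along(kept)) for (b in seq_along(kept)) if (a < b)
        expect_lte(recoveryScore(kept[[a]], kept[[b]]), 0.25)
    expect_length(kept, 3L)

    # a converged small run yields a usable elite set
    m <- plantedTinyMatrix(seed = 32)
    run <- runPcoba(m, pcobaConfig("artificial", mu = 20L, nu = 10L,
                                   maxGen = 40L, Sg = 6L, Sc = 3L, R = 2L,
                                   seed = 2L))
    top <- topBiclusters(run, k = 3, maxOverlap = 0.25)
    expect_gte(length(top), 1L)
    for (a in seq_along(top)) for (b in seq_along(top)) if (a < b)
        expect_lte(recoveryScore(top[[a]], top[[b]]), 0.25)
})
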