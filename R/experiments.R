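.ALGORITHMS <- c("PCOBA", "GA", "CGA", "EDA")

# Per-generation score-evaluation cost of each algorithm (the minimum,
# guaranteed part; coevolutionary runs add a few evaluations for gene
# individuals left unpaired by the condition-driven sampling).
.perGenEvals <- function(algorithm, popSize, nu, R) {
    if (algorithm %in% c("PCOBA", "CGA")) R * nu else popSize
}

#' Budget-matched multi-run comparison of the four algorithms
#'
#' Runs each requested algorithm \code{nRuns} times (seeds
#' \code{baseSeed .. baseSeed + nRuns - 1}) on the same dataset under an
#' equal total score-evaluation budget, and aggregates the per-run best
#' biclusters into a summary table of mean and standard deviation (n-1
#' denominator) of fitness, residue, variance, volume and — when ground
#' truth is available — cell-Jaccard recovery against the best-matching
#' planted block. Equal budgets are enforced by stopping each run within
#' one generation of \code{budget} evaluations, so any two algorithms'
#' totals differ by at most one generation's worth.
#'
#' @param dataset a [PlantedDataset-class] (enables recovery scoring) or a
#'   plain numeric expression matrix.
#' @param algorithms character vector, subset of
#'   \code{c("PCOBA", "GA", "CGA", "EDA")}.
#' @param nRuns runs per algorithm.
#' @param budget total score evaluations allotted to every run.
#' @param baseSeed first RNG seed; run r of every algorithm uses seed
#'   \code{baseSeed + r - 1}.
#' @param pcobaConfig a [PcobaConfig-class] template for the PCOBA runs
#'   (its \code{maxGen} and \code{seed} are overridden).
#' @param baselineConfigs named list of [BaselineConfig-class] templates
#'   for \code{"GA"}, \code{"CGA"}, \code{"EDA"} (same overrides).
#' @param out optional path; when given, the summary is also written as a
#'   tab-separated table.
#' @return A data.frame with one row per algorithm (columns:
#'   \code{algorithm}, \code{dataset}, \code{nRuns}, mean/sd of fitness,
#'   residue, variance, volume, recovery, and \code{evalsMean}), with the
#'   per-run records attached as \code{attr(x, "runs")}.
#' @examples
#' \donttest{
#' d <- generatePreset("Ea", seed = 1)
#' runComparison(d, c("PCOBA", "GA"), nRuns = 2, budget = 2000,
#'               baseSeed = 1)
#' }
#' @export
runComparison <- function(dataset, algorithms = .ALGORITHMS, nRuns = 20L,
                          budget = 10000L, baseSeed = 1L,
                          pcobaConfig = NULL, baselineConfigs = list(),
                          out = NULL) {
    stopifnot(all(algorithms %in% .ALGORITHMS), nRuns >= 1L)
    truth <- NULL
    if (is(dataset, "PlantedDataset")) {
        truth <- truthBlocks(dataset)
        m <- exprMatrix(dataset)
        dsName <- presetName(dataset)
    } else {
        m <- dataset
        dsName <- "matrix"
    }
    if (is.null(pcobaConfig))
        pcobaConfig <- pcoba::pcobaConfig("artificial")
    perGen <- vapply(algorithms, function(a) {
        cfg <- if (a == "PCOBA") pcobaConfig else
            baselineConfigs[[a]] %||% baselineConfig(a)
        if (a == "PCOBA") .perGenEvals(a, cfg@mu, cfg@nu, cfg@R)
        else .perGenEvals(a, cfg@popSize, cfg@nu, cfg@R)
    }, numeric(1))
    if (budget < 2 * max(perGen))
        stop("budget of ", budget, " evaluations cannot cover the initial ",
             "population plus one generation for every algorithm ",
             "(largest generation costs ", max(perGen), ")")
    records <- list()
    for (alg in algorithms) {
        gensCap <- as.integer(ceiling(budget / min(perGen)) + 5L)
        for (r in seq_len(nRuns)) {
            seed <- as.integer(baseSeed + r - 1L)
            run <- switch(alg,
                PCOBA = {
                    cfg <- pcobaConfig
                    cfg@maxGen <- gensCap; cfg@seed <- seed
                    runPcoba(m, cfg, maxEvaluations = budget)
                },
                {
                    cfg <- baselineConfigs[[alg]] %||% baselineConfig(alg)
                    cfg@maxGen <- gensCap; cfg@seed <- seed
                    switch(alg,
                        GA = runGa(m, cfg, maxEvaluations = budget),
                        CGA = runCga(m, cfg, maxEvaluations = budget),
                        EDA = runEda(m, cfg, maxEvaluations = budget))
                })
            b <- bestBicluster(run)
            rec <- data.frame(
                algorithm = alg, seed = seed,
                fitness = biclusterScore(b), residue = residueScore(b),
                variance = varianceScore(b), volume = biclusterVolume(b),
                recovery = if (is.null(truth)) NA_real_ else
                    max(vapply(truth, function(tb) recoveryScore(b, tb),
                               numeric(1))),
                nEvaluations = evaluationCount(run))
            records[[length(records) + 1L]] <- rec
        }
    }
    runs <- do.call(rbind, records)
    agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
    summary <- do.call(rbind, lapply(algorithms, function(alg) {
        sub <- runs[runs$algorithm == alg, ]
        data.frame(
            algorithm = alg, dataset = dsName, nRuns = nRuns,
            fitnessMean = mean(sub$fitness), fitnessSd = stats::sd(sub$fitness),
            residueMean = mean(sub$residue), residueSd = stats::sd(sub$residue),
            varianceMean = mean(sub$variance), varianceSd = stats::sd(sub$variance),
            volumeMean = mean(sub$volume), volumeSd = stats::sd(sub$volume),
            recoveryMean = mean(sub$recovery), recoverySd = stats::sd(sub$recovery),
            evalsMean = mean(sub$nEvaluations))
    }))
    attr(summary, "runs") <- runs
    if (!is.null(out))
        utils::write.table(summary, out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    summary
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a per-generation trajectory report
#'
#' Writes the best-ever (fitness, H, V, volume) trajectory of a run as a
#' tab-separated table with a header row. The fitness column is checked to
#' be non-increasing — the best-ever bookkeeping invariant of every search
#' algorithm in this package.
#'
#' @param trajectory a trajectory data.frame (see
#'   [BiclusterRun-class]) or a [BiclusterRun-class] object.
#' @param out output TSV path.
#' @return Invisibly, \code{out}.
#' @export
trajectoryReport <- function(trajectory, out) {
    if (is(trajectory, "BiclusterRun")) trajectory <- trajectory(trajectory)
    stopifnot(is.data.frame(trajectory), nrow(trajectory) >= 1L,
              all(c("generation", "fitness", "H", "V", "volume") %in%
                  names(trajectory)))
    if (any(diff(trajectory$fitness) > 1e-12))
        stop("trajectory fitness must be non-increasing (best-ever values)")
    utils::write.table(trajectory, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(out)
}

#' Average best-fitness trajectories across runs
#'
#' Truncates all trajectories to the shortest common generation count and
#' returns the per-generation mean of each tracked quantity — the data
#' behind averaged convergence plots.
#'
#' @param runs list of [BiclusterRun-class] objects (or trajectory
#'   data.frames).
#' @return A data.frame with columns \code{generation}, \code{fitness},
#'   \code{H}, \code{V}, \code{volume} (means over runs).
#' @export
averageTrajectories <- function(runs) {
    trajs <- lapply(runs, function(r)
        if (is(r, "BiclusterRun")) trajectory(r) else r)
    n <- min(vapply(trajs, nrow, integer(1)))
    stopifnot(n >= 1L)
    out <- trajs[[1L]][seq_len(n), , drop = FALSE]
    for (col in c("fitness", "H", "V", "volume"))
        out[[col]] <- rowMeans(vapply(trajs, function(t) t[[col]][seq_len(n)],
                                      numeric(n)))
    out
}

#' Extract the k best mutually distinct biclusters
#'
#' Sorts candidate biclusters (e.g. the final-population elites of one or
#' several runs) by score and greedily keeps each one whose cell-Jaccard
#' overlap with every already-kept bicluster is at most \code{maxOverlap} —
#' a simple deduplication policy for reporting the "k best biclusters" of
#' a run.
#'
#' @param candidates list of [Bicluster-class] objects, or a
#'   [BiclusterRun-class] (its elites are used).
#' @param k maximum number of biclusters to return.
#' @param maxOverlap maximum allowed pairwise cell-Jaccard in
#'   \eqn{[0, 1)}; identical decodings (overlap 1) are always removed.
#' @return A list of up to \code{k} [Bicluster-class] objects sorted by
#'   score.
#' @export
topBiclusters <- function(candidates, k = 10L, maxOverlap = 0.25) {
    if (is(candidates, "BiclusterRun"))
        candidates <- eliteBiclusters(candidates)
    stopifnot(k >= 1L, maxOverlap >= 0, maxOverlap < 1)
    candidates <- candidates[order(vapply(candidates,
                                          function(b) b@score, numeric(1)))]
    kept <- list()
    for (b in candidates) {
        if (length(kept) >= k) break
        ok <- all(vapply(kept, function(x) recoveryScore(b, x) <= maxOverlap,
                         logical(1)))
        if (ok) kept[[length(kept) + 1L]] <- b
    }
    kept
}
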