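#' Baseline algorithm configuration
#'
#' Constructs a [BaselineConfig-class] for one of the three comparison
#' algorithms. Defaults follow the published setup: GA and CGA use
#' population size 100 with per-bit mutation rate 0.05, roulette
#' (fitness-proportional) selection and no crossover; the EDA uses the PBIL
#' probability-vector update (rate 0.2 on the top 20\% of the population)
#' with the half-sampling / half-mutation offspring scheme at mutation rate
#' 0.01, like PCOBA.
#'
#' @param algorithm one of \code{"GA"}, \code{"CGA"}, \code{"EDA"}.
#' @param popSize population size (gene population for CGA).
#' @param nu condition population size (CGA only).
#' @param maxGen number of generations.
#' @param mutationRate per-bit flip probability (default 0.05 for GA/CGA,
#'   0.01 for EDA).
#' @param scoreParams a [ScoreParams-class]; defaults to the
#'   \code{"artificial"} preset.
#' @param pbilRate PBIL learning rate (EDA only).
#' @param eliteFraction fraction of the population used as PBIL elites
#'   (EDA only).
#' @param R collaborators per condition individual (CGA only; default
#'   \code{max(1, ceiling(0.1 * nu))}).
#' @param sampleFraction probability-vector offspring fraction (EDA only).
#' @param pInit initial per-bit inclusion probability.
#' @param seed integer RNG seed.
#' @return A validated [BaselineConfig-class].
#' @export
baselineConfig <- function(algorithm = c("GA", "CGA", "EDA"),
                           popSize = 100L, nu = 50L, maxGen = 100L,
                           mutationRate = NULL, scoreParams = NULL,
                           pbilRate = 0.2, eliteFraction = 0.2,
                           R = NULL, sampleFraction = 0.5,
                           pInit = 0.05, seed = 1L) {
    algorithm <- match.arg(algorithm)
    if (is.null(mutationRate))
        mutationRate <- if (algorithm == "EDA") 0.01 else 0.05
    if (is.null(scoreParams)) scoreParams <- pcoba::scoreParams("artificial")
    new("BaselineConfig",
        algorithm = algorithm, popSize = as.integer(popSize),
        nu = as.integer(nu), maxGen = as.integer(maxGen),
        mutationRate = mutationRate, scoreParams = scoreParams,
        pbilRate = pbilRate, eliteFraction = eliteFraction,
        R = as.integer(if (is.null(R)) max(1, ceiling(0.1 * nu)) else R),
        sampleFraction = sampleFraction, pInit = pInit,
        seed = as.integer(seed))
}

#' Fitness-proportional (roulette) selection for a minimization objective
#'
#' Selection weight of an individual with score \eqn{s} is
#' \eqn{1 / (s - s_{min} + 1)}: positive, bounded, and order-reversing so
#' that lower scores are selected more often. Returns \code{k} indices drawn
#' with replacement proportionally to weight. Uses the current RNG stream.
#'
#' @param fitness numeric score vector (lower is better).
#' @param k number of draws.
#' @return Integer vector of \code{k} selected indices.
#' @export
rouletteSelect <- function(fitness, k) {
    stopifnot(length(fitness) >= 1L, all(is.finite(fitness)))
    w <- 1 / (fitness - min(fitness) + 1)
    sample.int(length(fitness), k, replace = TRUE, prob = w)
}

# Repair a concatenated (N+M)-bit population so both the gene segment and
# the condition segment keep >= 2 set bits.
.repairConcat <- function(pop, N) {
    M <- ncol(pop) - N
    pop[, seq_len(N)] <- .repairMinBits(pop[, seq_len(N), drop = FALSE])
    pop[, N + seq_len(M)] <- .repairMinBits(pop[, N + seq_len(M),
                                                drop = FALSE])
    pop
}

# Score every row of a concatenated (N+M)-bit population; returns fitness,
# the best decoded pair, and the evaluation count.
.evaluateConcat <- function(pop, matrix, params) {
    N <- nrow(matrix)
    fit <- numeric(nrow(pop))
    best <- list(score = Inf)
    for (i in seq_len(nrow(pop))) {
        rows <- which(pop[i, seq_len(N)] == 1L)
        cols <- which(pop[i, -seq_len(N)] == 1L)
        s <- .scorePair(matrix, rows, cols, params, .SENTINEL)
        fit[i] <- s[1L]
        if (s[1L] < best$score)
            best <- list(score = s[1L], H = s[2L], V = s[3L],
                         volume = s[4L], rows = rows, cols = cols)
    }
    list(fit = fit, best = best, nEvals = nrow(pop))
}

.decodeConcatElites <- function(pop, fit, matrix, params, k) {
    N <- nrow(matrix)
    ord <- order(fit, seq_along(fit))[seq_len(min(k, nrow(pop)))]
    out <- list(); seen <- character()
    for (i in ord) {
        rows <- which(pop[i, seq_len(N)] == 1L)
        cols <- which(pop[i, -seq_len(N)] == 1L)
        if (length(rows) < 2L || length(cols) < 2L) next
        key <- paste(paste(rows, collapse = ","),
                     paste(cols, collapse = ","), sep = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        s <- .scorePair(matrix, rows, cols, params)
        out[[length(out) + 1L]] <-
            new("Bicluster", rows = rows, cols = cols, H = s[2L], V = s[3L],
                volume = s[4L], score = s[1L])
    }
    out[order(vapply(out, function(b) b@score, numeric(1)))]
}

#' Genetic algorithm baseline
#'
#' Single population of concatenated (N+M)-bit strings (first N bits select
#' genes, last M bits select conditions), evaluated directly with the shared
#' score. Reproduction is roulette selection on the transformed score (see
#' [rouletteSelect()]) followed by per-bit mutation; crossover is
#' deliberately absent. Deterministic given the config seed.
#'
#' @param matrix numeric expression matrix.
#' @param config a [BaselineConfig-class] with \code{algorithm = "GA"}.
#' @param maxEvaluations optional score-evaluation budget; the run stops at
#'   the end of the first generation whose cumulative evaluation count
#'   reaches it.
#' @return A [BiclusterRun-class].
#' @export
runGa <- function(matrix, config = baselineConfig("GA"),
                  maxEvaluations = Inf) {
    stopifnot(is.matrix(matrix), !anyNA(matrix), config@algorithm == "GA")
    validObject(config)
    N <- nrow(matrix); M <- ncol(matrix)
    .seededRng(config@seed)(function() {
        params <- config@scoreParams
        pop <- matrix(as.integer(
            stats::runif(config@popSize * (N + M)) < config@pInit),
            nrow = config@popSize)
        pop <- .repairConcat(pop, N)
        ev <- .evaluateConcat(pop, matrix, params)
        nEvals <- ev$nEvals
        bestEver <- ev$best
        traj <- .newTrajectory(config@maxGen)
        nGen <- 0L
        for (gen in seq_len(config@maxGen)) {
            if (nEvals >= maxEvaluations) break
            idx <- rouletteSelect(ev$fit, config@popSize)
            pop <- pop[idx, , drop = FALSE]
            if (config@mutationRate > 0) {
                flips <- matrix(
                    stats::runif(length(pop)) < config@mutationRate,
                    nrow = nrow(pop))
                pop <- (pop + flips) %% 2L
                storage.mode(pop) <- "integer"
            }
            pop <- .repairConcat(pop, N)
            ev <- .evaluateConcat(pop, matrix, params)
            nEvals <- nEvals + ev$nEvals
            if (ev$best$score < bestEver$score) bestEver <- ev$best
            traj[gen, -1L] <- c(bestEver$score, bestEver$H, bestEver$V,
                                bestEver$volume)
            nGen <- gen
        }
        traj <- traj[seq_len(nGen), , drop = FALSE]
        k <- max(1L, ceiling(config@eliteFraction * config@popSize))
        new("BiclusterRun", algorithm = "GA",
            best = .asBicluster(bestEver), trajectory = traj,
            elites = .decodeConcatElites(pop, ev$fit, matrix, params, k),
            nEvaluations = as.numeric(nEvals), seed = config@seed)
    })
}

#' Coevolutionary genetic algorithm baseline
#'
#' Two populations (N-bit gene subsets, M-bit condition subsets) evaluated
#' with PCOBA's collaborator scheme ([evaluateCoevolutionary()], including
#' R-subsampling and minimum-score fitness), but evolved with the GA's
#' operators: roulette selection plus per-bit mutation, no probability
#' vectors.
#'
#' @param matrix numeric expression matrix.
#' @param config a [BaselineConfig-class] with \code{algorithm = "CGA"};
#'   \code{popSize} is the gene population size, \code{nu} the condition
#'   population size.
#' @inheritParams runGa
#' @return A [BiclusterRun-class].
#' @export
runCga <- function(matrix, config = baselineConfig("CGA"),
                   maxEvaluations = Inf) {
    stopifnot(is.matrix(matrix), !anyNA(matrix), config@algorithm == "CGA")
    validObject(config)
    .seededRng(config@seed)(function() {
        params <- config@scoreParams
        popG <- initPopulation(config@popSize, nrow(matrix), config@pInit)
        popC <- initPopulation(config@nu, ncol(matrix), config@pInit)
        ev <- evaluateCoevolutionary(popG, popC, matrix, params, config@R)
        nEvals <- ev$nEvals
        bestEver <- ev$best
        traj <- .newTrajectory(config@maxGen)
        nGen <- 0L
        reproduce <- function(pop, fit) {
            pop <- pop[rouletteSelect(fit, nrow(pop)), , drop = FALSE]
            if (config@mutationRate > 0) {
                flips <- matrix(
                    stats::runif(length(pop)) < config@mutationRate,
                    nrow = nrow(pop))
                pop <- (pop + flips) %% 2L
                storage.mode(pop) <- "integer"
            }
            .repairMinBits(pop)
        }
        for (gen in seq_len(config@maxGen)) {
            if (nEvals >= maxEvaluations) break
            popG <- reproduce(popG, ev$fitG)
            popC <- reproduce(popC, ev$fitC)
            ev <- evaluateCoevolutionary(popG, popC, matrix, params,
                                         config@R)
            nEvals <- nEvals + ev$nEvals
            if (ev$best$score < bestEver$score) bestEver <- ev$best
            traj[gen, -1L] <- c(bestEver$score, bestEver$H, bestEver$V,
                                bestEver$volume)
            nGen <- gen
        }
        traj <- traj[seq_len(nGen), , drop = FALSE]
        k <- max(1L, ceiling(config@eliteFraction * config@popSize))
        new("BiclusterRun", algorithm = "CGA",
            best = .asBicluster(bestEver), trajectory = traj,
            elites = .decodeElites(popG, popC, ev, matrix, params, k),
            nEvaluations = as.numeric(nEvals), seed = config@seed)
    })
}

#' Estimation-of-distribution algorithm baseline
#'
#' Single population of concatenated (N+M)-bit strings with one PBIL
#' probability vector of length N+M, updated from the top
#' \code{eliteFraction} of the population each generation; offspring are
#' half-sampled from the probability vector and half-mutated from the top
#' half of the population, as in the PCOBA engine, but without
#' coevolutionary decomposition.
#'
#' @param matrix numeric expression matrix.
#' @param config a [BaselineConfig-class] with \code{algorithm = "EDA"}.
#' @inheritParams runGa
#' @return A [BiclusterRun-class].
#' @export
runEda <- function(matrix, config = baselineConfig("EDA"),
                   maxEvaluations = Inf) {
    stopifnot(is.matrix(matrix), !anyNA(matrix), config@algorithm == "EDA")
    validObject(config)
    N <- nrow(matrix); M <- ncol(matrix)
    .seededRng(config@seed)(function() {
        params <- config@scoreParams
        pop <- matrix(as.integer(
            stats::runif(config@popSize * (N + M)) < config@pInit),
            nrow = config@popSize)
        pop <- .repairConcat(pop, N)
        p <- rep(config@pInit, N + M)
        ev <- .evaluateConcat(pop, matrix, params)
        nEvals <- ev$nEvals
        bestEver <- ev$best
        traj <- .newTrajectory(config@maxGen)
        nGen <- 0L
        nElite <- max(1L, ceiling(config@eliteFraction * config@popSize))
        for (gen in seq_len(config@maxGen)) {
            if (nEvals >= maxEvaluations) break
            elites <- selectBest(pop, ev$fit, nElite)
            p <- updateProbability(p, elites, config@pbilRate)
            pop <- makeOffspring(p, pop, ev$fit, config@popSize,
                                 config@mutationRate, config@sampleFraction)
            pop <- .repairConcat(pop, N)
            ev <- .evaluateConcat(pop, matrix, params)
            nEvals <- nEvals + ev$nEvals
            if (ev$best$score < bestEver$score) bestEver <- ev$best
            traj[gen, -1L] <- c(bestEver$score, bestEver$H, bestEver$V,
                                bestEver$volume)
            nGen <- gen
        }
        traj <- traj[seq_len(nGen), , drop = FALSE]
        new("BiclusterRun", algorithm = "EDA",
            best = .asBicluster(bestEver), trajectory = traj,
            elites = .decodeConcatElites(pop, ev$fit, matrix, params,
                                         nElite),
            nEvaluations = as.numeric(nEvals), seed = config@seed)
    })
}
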