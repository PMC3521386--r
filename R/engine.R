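#' PCOBA engine configuration with published presets
#'
#' Constructs a [PcobaConfig-class]. Presets reproduce the published
#' parameter table: \code{"artificial"} (\eqn{\mu = 100}, \eqn{\nu = 50},
#' 100 generations, \eqn{\alpha = \beta = 0.2}, \eqn{S_g = 20},
#' \eqn{S_c = 10}, mutation rate 0.01, score preset \code{"artificial"}),
#' \code{"artificialLarge"} (\eqn{\mu = 1000}, 200 generations,
#' \eqn{S_g = 200}, score preset \code{"artificialLarge"}) for the
#' 1,500-gene benchmark, and \code{"real"} (\eqn{\mu = 1000},
#' \eqn{\nu = 100}, 500 generations, \eqn{S_g = 200}, \eqn{S_c = 20}).
#' \code{R} defaults to \code{max(1, ceiling(0.1 * nu))} collaborators per
#' condition individual.
#'
#' @param preset character(1) preset name.
#' @param mu,nu gene / condition population sizes.
#' @param maxGen number of generations.
#' @param scoreParams a [ScoreParams-class]; defaults to the matching preset.
#' @param alpha,beta PBIL learning rates in (0, 1).
#' @param Sg,Sc elite counts.
#' @param R collaborators sampled per condition individual
#'   (default \code{max(1, ceiling(0.1 * nu))}).
#' @param mutationRate per-bit flip probability for the mutation offspring.
#' @param sampleFraction fraction of offspring sampled from the probability
#'   vector.
#' @param pInit initial per-bit inclusion probability; the sparse default
#'   (0.05, with a floor of 2 indices per individual) seeds the search with
#'   small candidate submatrices, which is what lets the volume collapse to
#'   minimal coherent seeds and then grow (see [PcobaConfig-class]).
#' @param seed integer RNG seed.
#' @return A validated [PcobaConfig-class].
#' @examples
#' pcobaConfig("artificial", seed = 7)
#' @export
pcobaConfig <- function(preset = c("artificial", "artificialLarge", "real"),
                        mu = NULL, nu = NULL, maxGen = NULL,
                        scoreParams = NULL, alpha = 0.2, beta = 0.2,
                        Sg = NULL, Sc = NULL, R = NULL,
                        mutationRate = 0.01, sampleFraction = 0.5,
                        pInit = 0.05, seed = 1L) {
    preset <- match.arg(preset)
    def <- switch(preset,
        artificial = list(mu = 100L, nu = 50L, maxGen = 100L,
                          Sg = 20L, Sc = 10L, sp = "artificial"),
        artificialLarge = list(mu = 1000L, nu = 50L, maxGen = 200L,
                               Sg = 200L, Sc = 10L, sp = "artificialLarge"),
        real = list(mu = 1000L, nu = 100L, maxGen = 500L,
                    Sg = 200L, Sc = 20L, sp = "real"))
    mu <- as.integer(if (is.null(mu)) def$mu else mu)
    nu <- as.integer(if (is.null(nu)) def$nu else nu)
    if (is.null(scoreParams)) scoreParams <- scoreParams(def$sp)
    new("PcobaConfig",
        mu = mu, nu = nu,
        maxGen = as.integer(if (is.null(maxGen)) def$maxGen else maxGen),
        scoreParams = scoreParams, alpha = alpha, beta = beta,
        Sg = as.integer(if (is.null(Sg)) def$Sg else Sg),
        Sc = as.integer(if (is.null(Sc)) def$Sc else Sc),
        R = as.integer(if (is.null(R)) max(1, ceiling(0.1 * nu)) else R),
        mutationRate = mutationRate, sampleFraction = sampleFraction,
        pInit = pInit, seed = as.integer(seed))
}

# Sentinel score for pairs whose gene or condition set has < 2 members:
# larger than any attainable score on bounded expression data.
.SENTINEL <- 1e9

# Ensure every individual (row) selects at least 2 indices by setting
# additional uniformly chosen unset bits. 1 x m / n x 1 submatrices have
# identically zero residue and would hijack the search.
.repairMinBits <- function(pop, minBits = 2L) {
    counts <- rowSums(pop)
    for (i in which(counts < minBits)) {
        zero <- which(pop[i, ] == 0L)
        need <- minBits - counts[i]
        pick <- if (length(zero) == 1L) zero else
            sample(zero, min(need, length(zero)))
        pop[i, pick] <- 1L
    }
    pop
}

#' Create a random binary population
#'
#' Each of \code{count} individuals is a \code{length}-bit vector whose bits
#' are independently 1 with probability \code{pInit}; individuals with fewer
#' than 2 set bits are repaired by setting extra uniformly chosen bits
#' (degenerate single-row/column biclusters have identically zero residue).
#' Uses the current RNG stream unless \code{seed} is given.
#'
#' @param count number of individuals (>= 2).
#' @param length bits per individual (>= 2).
#' @param pInit per-bit inclusion probability in (0, 1).
#' @param seed optional integer seed for a self-contained reproducible draw.
#' @return An integer 0/1 matrix with \code{count} rows.
#' @export
initPopulation <- function(count, length, pInit = 0.5, seed = NULL) {
    stopifnot(count >= 2, length >= 2, pInit > 0, pInit < 1)
    draw <- function() {
        pop <- matrix(as.integer(stats::runif(count * length) < pInit),
                      nrow = count, ncol = length)
        .repairMinBits(pop)
    }
    if (is.null(seed)) draw() else .seededRng(seed)(draw)
}

.decodeRows <- function(pop) {
    lapply(seq_len(nrow(pop)), function(i) which(pop[i, ] == 1L))
}

#' Collaborator-based fitness of two coevolving populations
#'
#' For every condition individual \eqn{y_j}, \code{R} gene individuals are
#' drawn uniformly without replacement and each pair \eqn{(x, y_j)} is
#' scored; an individual's fitness is the minimum score over the pairs it
#' appeared in (cooperative credit: it is judged by its best collaborator).
#' Gene individuals left unpaired by the condition-driven sampling receive
#' one uniformly drawn collaborator so that every individual has a defined
#' fitness. Pairs in which either member selects fewer than 2 indices get a
#' large sentinel score. Uses the current RNG stream.
#'
#' @param popG integer 0/1 matrix, gene population (\eqn{\mu \times N}).
#' @param popC integer 0/1 matrix, condition population (\eqn{\nu \times M}).
#' @param matrix numeric expression matrix.
#' @param params a [ScoreParams-class].
#' @param R collaborators sampled per condition individual
#'   (\code{R = nrow(popG)} gives exhaustive pairing).
#' @return A list: \code{fitG}, \code{fitC} (fitness vectors),
#'   \code{partnerG}, \code{partnerC} (index of the best collaborator found
#'   for each individual), \code{best} (list with \code{score}, \code{H},
#'   \code{V}, \code{volume}, \code{rows}, \code{cols} of the generation's
#'   best pair) and \code{nEvals} (score evaluations spent).
#' @export
evaluateCoevolutionary <- function(popG, popC, matrix, params, R) {
    mu <- nrow(popG); nu <- nrow(popC)
    stopifnot(R >= 1L, R <= mu)
    rowsG <- .decodeRows(popG)
    rowsC <- .decodeRows(popC)
    fitG <- rep(Inf, mu); fitC <- rep(Inf, nu)
    partnerG <- rep(NA_integer_, mu); partnerC <- rep(NA_integer_, nu)
    paired <- logical(mu)
    best <- list(score = Inf)
    nEvals <- 0L
    scoreOne <- function(i, j) {
        s <- .scorePair(matrix, rowsG[[i]], rowsC[[j]], params, .SENTINEL)
        nEvals <<- nEvals + 1L
        if (s[1L] < fitG[i]) { fitG[i] <<- s[1L]; partnerG[i] <<- j }
        if (s[1L] < fitC[j]) { fitC[j] <<- s[1L]; partnerC[j] <<- i }
        if (s[1L] < best$score)
            best <<- list(score = s[1L], H = s[2L], V = s[3L],
                          volume = s[4L], rows = rowsG[[i]],
                          cols = rowsC[[j]])
        invisible(NULL)
    }
    for (j in seq_len(nu)) {
        collab <- if (R == mu) seq_len(mu) else sample.int(mu, R)
        for (i in collab) scoreOne(i, j)
        paired[collab] <- TRUE
    }
    for (i in which(!paired)) scoreOne(i, sample.int(nu, 1L))
    # sentinel floor: individuals that only ever met degenerate pairs
    fitG[!is.finite(fitG)] <- .SENTINEL
    fitC[!is.finite(fitC)] <- .SENTINEL
    list(fitG = fitG, fitC = fitC, partnerG = partnerG, partnerC = partnerC,
         best = best, nEvals = nEvals)
}

#' Select the k best individuals of a population
#'
#' Returns the \code{k} individuals of lowest fitness; ties are broken by
#' earlier population index, making selection deterministic.
#'
#' @param pop integer 0/1 population matrix (individuals in rows).
#' @param fitness numeric fitness vector, one value per row of \code{pop}.
#' @param k number of individuals to select.
#' @return The selected rows of \code{pop} as a matrix, with the attribute
#'   \code{"indices"} holding their original row indices in rank order.
#' @export
selectBest <- function(pop, fitness, k) {
    stopifnot(k >= 1L, k <= nrow(pop), length(fitness) == nrow(pop))
    if (anyNA(fitness))
        stop("fitness has not been assigned for all individuals")
    ord <- order(fitness, seq_along(fitness))[seq_len(k)]
    out <- pop[ord, , drop = FALSE]
    attr(out, "indices") <- ord
    out
}

#' PBIL update of a probability vector
#'
#' Moves each per-bit inclusion probability toward the bit frequency of the
#' selected elite individuals:
#' \eqn{p_i \leftarrow (1 - rate) p_i + rate \cdot \bar{x}_i}, then clamps
#' to \code{clamp} (default \eqn{[0.01, 0.99]}) so that no bit fixes
#' irreversibly.
#'
#' @param p numeric probability vector.
#' @param selected integer 0/1 matrix of elite individuals (rows), same bit
#'   length as \code{p}.
#' @param rate learning rate in (0, 1).
#' @param clamp length-2 numeric, lower/upper clamp bounds.
#' @return The updated, clamped probability vector.
#' @export
updateProbability <- function(p, selected, rate, clamp = c(0.01, 0.99)) {
    stopifnot(rate > 0, rate < 1, is.matrix(selected),
              ncol(selected) == length(p), nrow(selected) >= 1L)
    p <- (1 - rate) * p + rate * colMeans(selected)
    pmin(pmax(p, clamp[1L]), clamp[2L])
}

#' Generate an offspring population by sampling and mutation
#'
#' Mirrors the half/half offspring scheme: \code{ceiling(sampleFraction *
#' popSize)} offspring are drawn bitwise-independently from the probability
#' vector \code{p}; the remainder are produced by per-bit flip mutation
#' (probability \code{mutationRate}) applied to parents cycled from the top
#' 50\% of the current population ranked by fitness. All offspring are
#' repaired to at least 2 set bits. Uses the current RNG stream.
#'
#' @param p numeric per-bit probability vector.
#' @param pop current population matrix.
#' @param fitness fitness vector for \code{pop} (ranks the mutation parents).
#' @param popSize number of offspring to produce.
#' @param mutationRate per-bit flip probability.
#' @param sampleFraction fraction of offspring sampled from \code{p}.
#' @return An integer 0/1 matrix with \code{popSize} rows.
#' @export
makeOffspring <- function(p, pop, fitness, popSize = nrow(pop),
                          mutationRate = 0.01, sampleFraction = 0.5) {
    len <- length(p)
    stopifnot(ncol(pop) == len, length(fitness) == nrow(pop))
    nSample <- ceiling(sampleFraction * popSize)
    nMut <- popSize - nSample
    parts <- list()
    if (nSample > 0L) {
        u <- matrix(stats::runif(nSample * len), nrow = nSample)
        parts$sampled <-
            matrix(as.integer(u < rep(p, each = nSample)), nrow = nSample)
    }
    if (nMut > 0L) {
        nTop <- max(1L, floor(nrow(pop) / 2))
        topIdx <- order(fitness, seq_along(fitness))[seq_len(nTop)]
        parents <- pop[rep_len(topIdx, nMut), , drop = FALSE]
        if (mutationRate > 0) {
            flips <- matrix(stats::runif(nMut * len) < mutationRate,
                            nrow = nMut)
            parents <- (parents + flips) %% 2L
        }
        parts$mutated <- parents
    }
    off <- do.call(rbind, parts)
    storage.mode(off) <- "integer"
    .repairMinBits(off)
}

.asBicluster <- function(best) {
    new("Bicluster", rows = sort(as.integer(best$rows)),
        cols = sort(as.integer(best$cols)),
        H = best$H, V = best$V, volume = best$volume, score = best$score)
}

# Decode the top k individuals of a coevolutionary population with their
# best partners into distinct Bicluster objects, sorted by score.
.decodeElites <- function(popG, popC, ev, matrix, params, k) {
    ord <- order(ev$fitG, seq_along(ev$fitG))[seq_len(min(k, nrow(popG)))]
    out <- list(); seen <- character()
    for (i in ord) {
        j <- ev$partnerG[i]
        if (is.na(j)) next
        rows <- which(popG[i, ] == 1L)
        cols <- which(popC[j, ] == 1L)
        if (length(rows) < 2L || length(cols) < 2L) next
        key <- paste(paste(rows, collapse = ","),
                     paste(cols, collapse = ","), sep = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        s <- .scorePair(matrix, rows, cols, params)
        out[[length(out) + 1L]] <-
            new("Bicluster", rows = rows, cols = cols,
                H = s[2L], V = s[3L], volume = s[4L], score = s[1L])
    }
    out[order(vapply(out, function(b) b@score, numeric(1)))]
}

.newTrajectory <- function(n) {
    data.frame(generation = seq_len(n), fitness = rep(NA_real_, n),
               H = rep(NA_real_, n), V = rep(NA_real_, n),
               volume = rep(NA_real_, n))
}

#' Run the probabilistic coevolutionary biclustering algorithm
#'
#' Coevolves a population of gene subsets and a population of condition
#' subsets against the shared residue/variance/volume score. Each
#' generation: collaborator-based fitness evaluation (with R-subsampling of
#' the gene population), elite selection (\eqn{S_g}, \eqn{S_c}), PBIL update
#' of the two per-bit probability vectors, and offspring generation (half
#' sampled from the probability vectors, half per-bit mutations of the top
#' half of the population). The best (gene set, condition set) pair ever
#' scored is returned, together with a per-generation trajectory of the
#' best-ever fitness, residue, variance and volume. Fully deterministic
#' given \code{config}'s seed.
#'
#' @param matrix numeric expression matrix (genes x conditions), no missing
#'   values.
#' @param config a [PcobaConfig-class]; see [pcobaConfig()].
#' @param maxEvaluations optional score-evaluation budget; the run stops at
#'   the end of the first generation whose cumulative evaluation count
#'   reaches it (used by [runComparison()] for budget-matched comparisons).
#' @return A [BiclusterRun-class] object.
#' @examples
#' d <- generatePreset("Ea", seed = 1)
#' cfg <- pcobaConfig("artificial", maxGen = 10L, seed = 1L)
#' run <- runPcoba(exprMatrix(d), cfg)
#' bestBicluster(run)
#' @export
runPcoba <- function(matrix, config = pcobaConfig(), maxEvaluations = Inf) {
    stopifnot(is.matrix(matrix), is.numeric(matrix), !anyNA(matrix))
    validObject(config)
    .seededRng(config@seed)(function() {
        params <- config@scoreParams
        popG <- initPopulation(config@mu, nrow(matrix), config@pInit)
        popC <- initPopulation(config@nu, ncol(matrix), config@pInit)
        pG <- rep(config@pInit, nrow(matrix))
        pC <- rep(config@pInit, ncol(matrix))
        ev <- evaluateCoevolutionary(popG, popC, matrix, params, config@R)
        nEvals <- ev$nEvals
        bestEver <- ev$best
        traj <- .newTrajectory(config@maxGen)
        nGen <- 0L
        for (gen in seq_len(config@maxGen)) {
            if (nEvals >= maxEvaluations) break
            elitesG <- selectBest(popG, ev$fitG, config@Sg)
            elitesC <- selectBest(popC, ev$fitC, config@Sc)
            pG <- updateProbability(pG, elitesG, config@alpha)
            pC <- updateProbability(pC, elitesC, config@beta)
            popG <- makeOffspring(pG, popG, ev$fitG, config@mu,
                                  config@mutationRate, config@sampleFraction)
            popC <- makeOffspring(pC, popC, ev$fitC, config@nu,
                                  config@mutationRate, config@sampleFraction)
            ev <- evaluateCoevolutionary(popG, popC, matrix, params,
                                         config@R)
            nEvals <- nEvals + ev$nEvals
            if (ev$best$score < bestEver$score) bestEver <- ev$best
            traj[gen, -1L] <- c(bestEver$score, bestEver$H, bestEver$V,
                                bestEver$volume)
            nGen <- gen
        }
        traj <- traj[seq_len(nGen), , drop = FALSE]
        elites <- .decodeElites(popG, popC, ev, matrix, params, config@Sg)
        new("BiclusterRun", algorithm = "PCOBA",
            best = .asBicluster(bestEver), trajectory = traj,
            elites = elites, nEvaluations = as.numeric(nEvals),
            seed = config@seed)
    })
}

#' @rdname BiclusterRun-class
#' @export
setMethod("bestBicluster", "BiclusterRun", function(x) x@best)

#' @rdname BiclusterRun-class
#' @export
setMethod("trajectory", "BiclusterRun", function(x) x@trajectory)

#' @rdname BiclusterRun-class
#' @export
setMethod("eliteBiclusters", "BiclusterRun", function(x) x@elites)

#' @rdname BiclusterRun-class
#' @export
setMethod("evaluationCount", "BiclusterRun", function(x) x@nEvaluations)

setMethod("show", "BiclusterRun", function(object) {
    cat(sprintf("%s run (seed %d, %g score evaluations)\n",
                object@algorithm, object@seed, object@nEvaluations))
    b <- object@best
    cat(sprintf("best: %d x %d, H = %.4g, V = %.4g, score = %.4g\n",
                length(b@rows), length(b@cols), b@H, b@V, b@score))
    cat(sprintf("%d distinct elite bicluster(s); trajectory of %d generation(s)\n",
                length(object@elites), nrow(object@trajectory)))
})
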