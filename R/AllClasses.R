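#' @import methods
NULL

#' Parameters of the bicluster score function
#'
#' Bundles the weights of the three-term objective
#' \eqn{Score = RES + VAR + VOL} that every search algorithm in this package
#' minimizes: \code{delta} is the residue cutoff defining a
#' \eqn{\delta}-bicluster, \code{wB} weights the inverse row variance,
#' \code{wV} weights the volume term and \code{wG}/\code{wC} balance the gene
#' against the condition contribution inside it.
#'
#' Two algebraic forms of the volume term are supported. The default,
#' \code{"reciprocal_cardinality"}, is \eqn{w_v (w_g/|I| + w_c/|J|)}: it
#' decreases as the bicluster grows, so minimizing the score rewards large
#' biclusters, consistent with the stated search objective. The alternative
#' \code{"literal_fraction"} form \eqn{w_v (w_g |I|/N + w_c |J|/M)} grows with
#' size and is retained only for fidelity experiments; see the methods
#' vignette for the full discussion.
#'
#' @slot delta numeric(1), residue cutoff \eqn{\delta > 0}.
#' @slot wB numeric(1), variance weight \eqn{w_b \ge 0}.
#' @slot wV numeric(1), volume weight \eqn{w_v \ge 0}.
#' @slot wG,wC numeric(1) in [0, 1], gene/condition balance weights.
#' @slot volumeForm character(1), one of \code{"reciprocal_cardinality"}
#'   (default) or \code{"literal_fraction"}.
#' @slot variancePenalty numeric(1), the VAR value assigned to a degenerate
#'   flat bicluster (row variance below \code{varianceEps}).
#' @slot varianceEps numeric(1), threshold under which a row variance is
#'   treated as zero.
#'
#' @seealso [scoreParams()] for the user-facing constructor with the
#'   published parameter presets.
#' @exportClass ScoreParams
setClass("ScoreParams",
    representation(
        delta = "numeric",
        wB = "numeric",
        wV = "numeric",
        wG = "numeric",
        wC = "numeric",
        volumeForm = "character",
        variancePenalty = "numeric",
        varianceEps = "numeric"
    ),
    prototype(
        delta = 20, wB = 0.5, wV = 10, wG = 0.9, wC = 0.1,
        volumeForm = "reciprocal_cardinality",
        variancePenalty = 1e6, varianceEps = 1e-12
    )
)

setValidity("ScoreParams", function(object) {
    msg <- character()
    if (length(object@delta) != 1L || !is.finite(object@delta) ||
        object@delta <= 0)
        msg <- c(msg, "'delta' must be a single positive number")
    for (w in c("wB", "wV")) {
        v <- slot(object, w)
        if (length(v) != 1L || !is.finite(v) || v < 0)
            msg <- c(msg, sprintf("'%s' must be a single non-negative number", w))
    }
    for (w in c("wG", "wC")) {
        v <- slot(object, w)
        if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
            msg <- c(msg, sprintf("'%s' must be a single number in [0, 1]", w))
    }
    if (length(object@volumeForm) != 1L ||
        !object@volumeForm %in% c("reciprocal_cardinality", "literal_fraction"))
        msg <- c(msg, "'volumeForm' must be 'reciprocal_cardinality' or 'literal_fraction'")
    if (object@variancePenalty <= 0)
        msg <- c(msg, "'variancePenalty' must be positive")
    if (length(msg)) msg else TRUE
})

#' Bicluster: a scored submatrix (I, J)
#'
#' A bicluster selects a subset \eqn{I} of rows (genes) and a subset \eqn{J}
#' of columns (conditions) of an expression matrix. Alongside the index sets
#' the object caches the quality measures computed at construction time: the
#' mean squared residue \eqn{H_{IJ}}, the row variance \eqn{V_{IJ}}, the
#' volume \eqn{|I| \cdot |J|} and the combined score (lower is better).
#'
#' @slot rows integer vector, 1-based row indices \eqn{I} (sorted, unique).
#' @slot cols integer vector, 1-based column indices \eqn{J} (sorted, unique).
#' @slot H numeric(1), mean squared residue.
#' @slot V numeric(1), row variance.
#' @slot volume numeric(1), \code{length(rows) * length(cols)}.
#' @slot score numeric(1), combined residue + variance + volume score.
#'
#' @seealso [scoreBicluster()], which constructs scored `Bicluster` objects.
#' @exportClass Bicluster
setClass("Bicluster",
    representation(
        rows = "integer",
        cols = "integer",
        H = "numeric",
        V = "numeric",
        volume = "numeric",
        score = "numeric"
    ),
    prototype(rows = integer(), cols = integer(),
              H = NA_real_, V = NA_real_, volume = 0, score = NA_real_)
)

setValidity("Bicluster", function(object) {
    msg <- character()
    if (anyDuplicated(object@rows) || anyDuplicated(object@cols))
        msg <- c(msg, "row/column index sets must not contain duplicates")
    if (length(object@rows) && any(object@rows < 1L))
        msg <- c(msg, "row indices must be >= 1")
    if (length(object@cols) && any(object@cols < 1L))
        msg <- c(msg, "column indices must be >= 1")
    if (!isTRUE(all.equal(object@volume,
                          length(object@rows) * length(object@cols))))
        msg <- c(msg, "'volume' must equal length(rows) * length(cols)")
    if (is.finite(object@H) && object@H < -1e-9)
        msg <- c(msg, "'H' must be non-negative")
    if (is.finite(object@V) && object@V < -1e-9)
        msg <- c(msg, "'V' must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Configuration of the PCOBA coevolutionary engine
#'
#' Holds the search hyper-parameters of the probabilistic coevolutionary
#' biclustering algorithm: the two population sizes (\code{mu} gene-subset
#' individuals of length N, \code{nu} condition-subset individuals of length
#' M), the generation budget, the PBIL learning rates \code{alpha} and
#' \code{beta}, the elite counts \code{Sg}/\code{Sc}, the number \code{R} of
#' collaborators sampled per condition individual, and the offspring scheme
#' (fraction sampled from the probability vector vs. produced by per-bit
#' mutation of good parents).
#'
#' @slot mu,nu integer(1), gene and condition population sizes.
#' @slot maxGen integer(1), number of generations (0 = initial population only).
#' @slot scoreParams a [ScoreParams-class] object.
#' @slot alpha,beta numeric(1) in (0, 1), PBIL update rates for the gene and
#'   condition probability vectors.
#' @slot Sg,Sc integer(1), elite counts used for the PBIL updates.
#' @slot R integer(1), collaborators sampled per condition individual.
#' @slot mutationRate numeric(1), per-bit flip probability of the mutation
#'   half of the offspring.
#' @slot sampleFraction numeric(1), fraction of each offspring population
#'   drawn from the probability vector (default 0.5).
#' @slot pInit numeric(1), initial per-bit inclusion probability. The
#'   default 0.05 initializes individuals as sparse subsets (at least 2
#'   indices after repair): biclusters are small submatrices, and sparse
#'   seeds let the search collapse to minimal coherent submatrices and then
#'   grow them, reproducing the characteristic volume-minimum-then-growth
#'   trajectory; dense initialization instead drives premature collapse of
#'   the condition population (see the methods vignette).
#' @slot seed integer(1), RNG seed making the run fully reproducible.
#'
#' @seealso [pcobaConfig()] for the constructor with published presets.
#' @exportClass PcobaConfig
setClass("PcobaConfig",
    representation(
        mu = "integer", nu = "integer", maxGen = "integer",
        scoreParams = "ScoreParams",
        alpha = "numeric", beta = "numeric",
        Sg = "integer", Sc = "integer", R = "integer",
        mutationRate = "numeric", sampleFraction = "numeric",
        pInit = "numeric", seed = "integer"
    ),
    prototype(
        mu = 100L, nu = 50L, maxGen = 100L,
        alpha = 0.2, beta = 0.2, Sg = 20L, Sc = 10L, R = 5L,
        mutationRate = 0.01, sampleFraction = 0.5, pInit = 0.05, seed = 1L
    )
)

setValidity("PcobaConfig", function(object) {
    msg <- character()
    if (object@mu < 2L || object@nu < 2L)
        msg <- c(msg, "population sizes 'mu' and 'nu' must be >= 2")
    if (object@maxGen < 0L)
        msg <- c(msg, "'maxGen' must be >= 0")
    if (object@Sg < 1L || object@Sg > object@mu)
        msg <- c(msg, "'Sg' must satisfy 1 <= Sg <= mu")
    if (object@Sc < 1L || object@Sc > object@nu)
        msg <- c(msg, "'Sc' must satisfy 1 <= Sc <= nu")
    if (object@R < 1L || object@R > object@mu)
        msg <- c(msg, "'R' must satisfy 1 <= R <= mu (collaborators are gene individuals)")
    for (w in c("alpha", "beta")) {
        v <- slot(object, w)
        if (v <= 0 || v >= 1)
            msg <- c(msg, sprintf("'%s' must lie in (0, 1)", w))
    }
    if (object@mutationRate < 0 || object@mutationRate > 1)
        msg <- c(msg, "'mutationRate' must lie in [0, 1]")
    if (object@sampleFraction < 0 || object@sampleFraction > 1)
        msg <- c(msg, "'sampleFraction' must lie in [0, 1]")
    if (object@pInit <= 0 || object@pInit >= 1)
        msg <- c(msg, "'pInit' must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Configuration of the evolutionary baseline algorithms
#'
#' Shared configuration for the three comparison algorithms: \code{"GA"}
#' (single population of (N+M)-bit strings, fitness-proportional selection
#' plus mutation, no crossover), \code{"CGA"} (two populations with the
#' coevolutionary collaborator evaluation of PCOBA but roulette + mutation
#' offspring) and \code{"EDA"} (single population with one concatenated PBIL
#' probability vector and the half-sampling / half-mutation offspring scheme).
#'
#' @slot algorithm character(1), one of \code{"GA"}, \code{"CGA"}, \code{"EDA"}.
#' @slot popSize integer(1), (gene) population size.
#' @slot nu integer(1), condition population size (CGA only).
#' @slot maxGen integer(1), number of generations.
#' @slot mutationRate numeric(1), per-bit flip probability.
#' @slot scoreParams a [ScoreParams-class] object.
#' @slot pbilRate numeric(1), PBIL learning rate (EDA only).
#' @slot eliteFraction numeric(1), fraction of the population used as PBIL
#'   elites (EDA only).
#' @slot R integer(1), collaborators per condition individual (CGA only).
#' @slot sampleFraction numeric(1), probability-vector offspring fraction
#'   (EDA only).
#' @slot pInit numeric(1), initial per-bit inclusion probability.
#' @slot seed integer(1), RNG seed.
#'
#' @seealso [baselineConfig()], [runGa()], [runCga()], [runEda()].
#' @exportClass BaselineConfig
setClass("BaselineConfig",
    representation(
        algorithm = "character",
        popSize = "integer", nu = "integer", maxGen = "integer",
        mutationRate = "numeric",
        scoreParams = "ScoreParams",
        pbilRate = "numeric", eliteFraction = "numeric",
        R = "integer", sampleFraction = "numeric",
        pInit = "numeric", seed = "integer"
    ),
    prototype(
        algorithm = "GA", popSize = 100L, nu = 50L, maxGen = 100L,
        mutationRate = 0.05, pbilRate = 0.2, eliteFraction = 0.2,
        R = 5L, sampleFraction = 0.5, pInit = 0.05, seed = 1L
    )
)

setValidity("BaselineConfig", function(object) {
    msg <- character()
    if (!object@algorithm %in% c("GA", "CGA", "EDA"))
        msg <- c(msg, "'algorithm' must be one of 'GA', 'CGA', 'EDA'")
    if (object@popSize < 2L)
        msg <- c(msg, "'popSize' must be >= 2")
    if (object@algorithm == "CGA" && object@nu < 2L)
        msg <- c(msg, "'nu' must be >= 2 for CGA")
    if (object@maxGen < 0L)
        msg <- c(msg, "'maxGen' must be >= 0")
    if (object@mutationRate < 0 || object@mutationRate > 1)
        msg <- c(msg, "'mutationRate' must lie in [0, 1]")
    if (object@pbilRate <= 0 || object@pbilRate >= 1)
        msg <- c(msg, "'pbilRate' must lie in (0, 1)")
    if (object@eliteFraction <= 0 || object@eliteFraction > 1)
        msg <- c(msg, "'eliteFraction' must lie in (0, 1]")
    if (object@algorithm == "CGA" &&
        (object@R < 1L || object@R > object@popSize))
        msg <- c(msg, "'R' must satisfy 1 <= R <= popSize for CGA")
    if (length(msg)) msg else TRUE
})

#' Synthetic expression matrix with planted bicluster ground truth
#'
#' Couples a generated expression matrix with the index sets of the coherent
#' blocks planted into it, enabling recovery scoring of any biclustering
#' result against ground truth.
#'
#' @slot matrix numeric matrix with unique gene rownames and condition
#'   colnames.
#' @slot truth list; each element is a \code{list(rows = , cols = )} pair of
#'   integer index vectors for one planted block.
#' @slot specName character(1), one of \code{"Ea"}, \code{"Eb"}, \code{"Ec"}
#'   or \code{"custom"}.
#'
#' @seealso [generatePreset()], [recoveryScore()].
#' @exportClass PlantedDataset
setClass("PlantedDataset",
    representation(
        matrix = "matrix",
        truth = "list",
        specName = "character"
    )
)

setValidity("PlantedDataset", function(object) {
    msg <- character()
    m <- object@matrix
    if (!is.numeric(m) || nrow(m) < 2L || ncol(m) < 2L)
        msg <- c(msg, "'matrix' must be a numeric matrix with >= 2 rows and columns")
    for (b in object@truth) {
        if (!is.list(b) || !all(c("rows", "cols") %in% names(b))) {
            msg <- c(msg, "each truth block must be a list(rows=, cols=)")
            next
        }
        if (any(b$rows < 1L) || any(b$rows > nrow(m)) ||
            any(b$cols < 1L) || any(b$cols > ncol(m)))
            msg <- c(msg, "truth index sets must lie within matrix bounds")
    }
    if (length(object@truth) > 1L) {
        allRows <- unlist(lapply(object@truth, `[[`, "rows"))
        if (anyDuplicated(allRows))
            msg <- c(msg, "planted blocks must occupy disjoint row sets")
    }
    if (length(msg)) msg else TRUE
})

#' Result of one biclustering run
#'
#' Returned by [runPcoba()], [runGa()], [runCga()] and [runEda()]: the
#' best-ever bicluster, the per-generation trajectory of the best-ever
#' solution's fitness and quality measures, the distinct elite biclusters
#' decoded from the final population(s), and the number of score evaluations
#' spent (the budget currency of the comparison experiments).
#'
#' @slot algorithm character(1), which search algorithm produced the result.
#' @slot best a [Bicluster-class], the best solution found over the run.
#' @slot trajectory data.frame with one row per generation and columns
#'   \code{generation}, \code{fitness}, \code{H}, \code{V}, \code{volume}
#'   (best-ever values, so \code{fitness} is non-increasing).
#' @slot elites list of distinct [Bicluster-class] objects decoded from the
#'   final population's best individuals, sorted by score.
#' @slot nEvaluations numeric(1), total score evaluations performed.
#' @slot seed integer(1), seed the run was started with.
#'
#' @exportClass BiclusterRun
setClass("BiclusterRun",
    representation(
        algorithm = "character",
        best = "Bicluster",
        trajectory = "data.frame",
        elites = "list",
        nEvaluations = "numeric",
        seed = "integer"
    )
)
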