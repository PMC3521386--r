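#' Specification of one planted coherent block
#'
#' A planted block follows the additive coherence model
#' \eqn{e_{ij} = a_i + b_j + \epsilon_{ij}} with gene effects
#' \eqn{a_i \sim N(0, rowEffectSd)}, condition effects \eqn{b_j} equally
#' spaced across \code{colEffectRange} (randomly permuted), and noise
#' \eqn{\epsilon_{ij} \sim N(0, noiseSd)}. The additive model has exactly
#' zero mean squared residue at zero noise; with noise the expected MSR is
#' approximately \eqn{noiseSd^2 (1 - 1/n)(1 - 1/m)}, so the default
#' \code{noiseSd = sqrt(targetMsr / 4)} keeps realized MSR comfortably
#' below \code{targetMsr}. The spread of the \eqn{b_j} keeps the block's
#' row variance high, distinguishing it from flat (trivial) biclusters.
#'
#' @param nRows,nCols block dimensions (>= 2).
#' @param targetMsr upper bound the realized block MSR must satisfy.
#' @param rowEffectSd standard deviation of the per-gene offsets.
#' @param colEffectRange length-2 numeric range spanned by the condition
#'   effects.
#' @param noiseSd standard deviation of the i.i.d. noise.
#' @return A validated list of class \code{"BlockSpec"}.
#' @export
blockSpec <- function(nRows, nCols, targetMsr,
                      rowEffectSd = 10,
                      colEffectRange = c(50, 450),
                      noiseSd = sqrt(targetMsr / 4)) {
    stopifnot(nRows >= 2, nCols >= 2, targetMsr > 0, rowEffectSd >= 0,
              length(colEffectRange) == 2L,
              colEffectRange[1L] < colEffectRange[2L], noiseSd >= 0)
    structure(list(nRows = as.integer(nRows), nCols = as.integer(nCols),
                   targetMsr = targetMsr, rowEffectSd = rowEffectSd,
                   colEffectRange = colEffectRange, noiseSd = noiseSd),
              class = "BlockSpec")
}

#' Uniform background expression matrix
#'
#' Fills an \code{nRows x nCols} matrix with i.i.d. Uniform(\code{low},
#' \code{high}) values — the noise background into which coherent blocks
#' are planted. Row names \code{g1..gN} and column names \code{c1..cM} are
#' attached. Uses the current RNG stream unless \code{seed} is given.
#'
#' @param nRows,nCols matrix dimensions (>= 2).
#' @param low,high uniform bounds, \code{low < high}.
#' @param seed optional integer seed for a self-contained draw.
#' @return A numeric matrix with dimnames.
#' @export
generateBackground <- function(nRows, nCols, low = 0, high = 500,
                               seed = NULL) {
    stopifnot(nRows >= 2, nCols >= 2, low < high)
    draw <- function() {
        matrix(stats::runif(nRows * nCols, low, high),
               nrow = nRows, ncol = nCols,
               dimnames = list(paste0("g", seq_len(nRows)),
                               paste0("c", seq_len(nCols))))
    }
    if (is.null(seed)) draw() else .seededRng(seed)(draw)
}

#' Plant one coherent block into a matrix
#'
#' Overwrites the submatrix at (\code{rows}, \code{cols}) with values drawn
#' from the additive model of \code{spec}, clipped to \code{clipRange}. The
#' realized block is regenerated (up to \code{maxAttempts} times) until its
#' mean squared residue is below \code{spec$targetMsr} and its row variance
#' is positive; entries outside the block are untouched. Uses the current
#' RNG stream.
#'
#' @param matrix numeric matrix to plant into.
#' @param spec a [blockSpec()] object.
#' @param rows,cols index sets of the block; lengths must match the spec.
#' @param clipRange length-2 numeric, values are clipped into this range
#'   (keeps planted values on the background scale).
#' @param maxAttempts regeneration budget before giving up.
#' @return The matrix with the block planted.
#' @export
plantBlock <- function(matrix, spec, rows, cols, clipRange = c(0, 500),
                       maxAttempts = 100L) {
    stopifnot(inherits(spec, "BlockSpec"),
              length(rows) == spec$nRows, length(cols) == spec$nCols,
              all(rows >= 1), all(rows <= nrow(matrix)),
              all(cols >= 1), all(cols <= ncol(matrix)),
              !anyDuplicated(rows), !anyDuplicated(cols))
    for (attempt in seq_len(maxAttempts)) {
        a <- stats::rnorm(spec$nRows, 0, spec$rowEffectSd)
        b <- sample(seq(spec$colEffectRange[1L], spec$colEffectRange[2L],
                        length.out = spec$nCols))
        block <- outer(a, b, "+") +
            matrix(stats::rnorm(spec$nRows * spec$nCols, 0, spec$noiseSd),
                   nrow = spec$nRows)
        block <- pmin(pmax(block, clipRange[1L]), clipRange[2L])
        cand <- matrix
        cand[rows, cols] <- block
        H <- meanSquaredResidue(cand, rows, cols)
        V <- rowVariance(cand, rows, cols)
        if (H < spec$targetMsr && V > 0)
            return(cand)
    }
    stop(sprintf(
        "could not realize a block with MSR < %g in %d attempts (last MSR %.3g)",
        spec$targetMsr, maxAttempts, H))
}

#' Generate a planted-bicluster benchmark preset
#'
#' The three benchmark layouts: \code{"Ea"} — a 100 x 20 uniform[0, 500]
#' background with one planted 16 x 9 block (target MSR 20); \code{"Eb"} —
#' 100 x 20 with three blocks of 16 x 9, 10 x 5 and 10 x 10 (each target
#' MSR 20); \code{"Ec"} — 1,500 x 30 with three 100 x 15 blocks (each
#' target MSR 300). Block row sets are drawn uniformly at random and are
#' disjoint across blocks; column sets are drawn independently per block
#' (the layouts' combined column counts exceed the matrix width, so
#' column-disjointness is impossible — row-disjointness alone guarantees
#' that no cell belongs to two blocks). Ground-truth index sets are
#' recorded. Fully reproducible given \code{seed}.
#'
#' @param name one of \code{"Ea"}, \code{"Eb"}, \code{"Ec"}.
#' @param seed integer RNG seed.
#' @param blockSpecs optional list of [blockSpec()] objects overriding the
#'   preset's default block specifications (lengths must match).
#' @return A [PlantedDataset-class].
#' @examples
#' d <- generatePreset("Eb", seed = 1)
#' length(truthBlocks(d)) # 3
#' @export
generatePreset <- function(name = c("Ea", "Eb", "Ec"), seed = 1L,
                           blockSpecs = NULL) {
    name <- match.arg(name)
    layout <- switch(name,
        Ea = list(dim = c(100L, 20L), blocks = list(c(16L, 9L)),
                  targetMsr = 20),
        Eb = list(dim = c(100L, 20L),
                  blocks = list(c(16L, 9L), c(10L, 5L), c(10L, 10L)),
                  targetMsr = 20),
        Ec = list(dim = c(1500L, 30L),
                  blocks = list(c(100L, 15L), c(100L, 15L), c(100L, 15L)),
                  targetMsr = 300))
    if (is.null(blockSpecs))
        blockSpecs <- lapply(layout$blocks, function(d)
            blockSpec(d[1L], d[2L], layout$targetMsr))
    stopifnot(length(blockSpecs) == length(layout$blocks))
    .seededRng(seed)(function() {
        m <- generateBackground(layout$dim[1L], layout$dim[2L], 0, 500)
        freeRows <- seq_len(nrow(m))
        truth <- vector("list", length(blockSpecs))
        for (k in seq_along(blockSpecs)) {
            sp <- blockSpecs[[k]]
            rows <- sort(sample(freeRows, sp$nRows))
            freeRows <- setdiff(freeRows, rows)
            cols <- sort(sample(ncol(m), sp$nCols))
            m <- plantBlock(m, sp, rows, cols, clipRange = c(0, 500))
            V <- rowVariance(m, rows, cols)
            if (V <= 500)
                stop("planted block row variance unexpectedly low: ", V)
            truth[[k]] <- list(rows = rows, cols = cols)
        }
        new("PlantedDataset", matrix = m, truth = truth, specName = name)
    })
}

#' Cell-level Jaccard recovery score
#'
#' Overlap between a found bicluster and a ground-truth block, measured on
#' matrix cells: \eqn{|cells(found) \cap cells(truth)| /
#' |cells(found) \cup cells(truth)|}. 1 for exact recovery, 0 for disjoint
#' submatrices.
#'
#' @param found a [Bicluster-class] or a \code{list(rows =, cols =)}.
#' @param truth a \code{list(rows =, cols =)} (e.g. one element of
#'   [truthBlocks()]) or a [Bicluster-class].
#' @return numeric(1) in [0, 1].
#' @export
recoveryScore <- function(found, truth) {
    ix <- function(x) {
        if (is(x, "Bicluster")) list(rows = x@rows, cols = x@cols) else x
    }
    f <- ix(found); t <- ix(truth)
    inter <- length(intersect(f$rows, t$rows)) *
        length(intersect(f$cols, t$cols))
    a <- length(f$rows) * length(f$cols)
    b <- length(t$rows) * length(t$cols)
    if (a + b == 0) return(0)
    inter / (a + b - inter)
}

#' @rdname PlantedDataset-class
#' @export
setMethod("exprMatrix", "PlantedDataset", function(x) x@matrix)

#' @rdname PlantedDataset-class
#' @export
setMethod("truthBlocks", "PlantedDataset", function(x) x@truth)

#' @rdname PlantedDataset-class
#' @export
setMethod("presetName", "PlantedDataset", function(x) x@specName)

setMethod("show", "PlantedDataset", function(object) {
    cat(sprintf("PlantedDataset '%s': %d x %d matrix, %d planted block(s)\n",
                object@specName, nrow(object@matrix), ncol(object@matrix),
                length(object@truth)))
    for (b in object@truth)
        cat(sprintf("  block: %d rows x %d cols, MSR = %.3g\n",
                    length(b$rows), length(b$cols),
                    meanSquaredResidue(object@matrix, b$rows, b$cols)))
})
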