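#' Score function parameters with published presets
#'
#' Constructs a [ScoreParams-class] object. The \code{preset} argument fills
#' in the parameter sets used in the original study: \code{"artificial"}
#' (\eqn{\delta = 20}, \eqn{w_b = 0.5}, \eqn{w_v = 10}, \eqn{w_g = 0.9},
#' \eqn{w_c = 0.1}) for the small planted-block benchmarks Ea/Eb,
#' \code{"artificialLarge"} (\eqn{\delta = 300}, \eqn{w_v = 30},
#' \eqn{w_g = 0.8}, \eqn{w_c = 0.2}) for the 1,500-gene benchmark Ec, and
#' \code{"real"} (\eqn{\delta = 250}, \eqn{w_v = 30}, \eqn{w_g = 0.8},
#' \eqn{w_c = 0.2}) for real expression data. Any named argument overrides
#' its preset value.
#'
#' @param preset character(1), one of \code{"artificial"},
#'   \code{"artificialLarge"}, \code{"real"}.
#' @param delta residue cutoff \eqn{\delta > 0}.
#' @param wB variance weight \eqn{w_b}.
#' @param wV volume weight \eqn{w_v}.
#' @param wG,wC gene/condition balance weights.
#' @param volumeForm \code{"reciprocal_cardinality"} (default) or
#'   \code{"literal_fraction"}; see [ScoreParams-class].
#' @param variancePenalty VAR value for degenerate zero-variance biclusters.
#' @param varianceEps threshold below which a variance counts as zero.
#' @return A validated [ScoreParams-class] object.
#' @examples
#' scoreParams()
#' scoreParams("real", wV = 20)
#' @export
scoreParams <- function(preset = c("artificial", "artificialLarge", "real"),
                        delta = NULL, wB = NULL, wV = NULL,
                        wG = NULL, wC = NULL,
                        volumeForm = "reciprocal_cardinality",
                        variancePenalty = 1e6, varianceEps = 1e-12) {
    preset <- match.arg(preset)
    def <- switch(preset,
        artificial      = list(delta = 20,  wB = 0.5, wV = 10, wG = 0.9, wC = 0.1),
        artificialLarge = list(delta = 300, wB = 0.5, wV = 30, wG = 0.8, wC = 0.2),
        real            = list(delta = 250, wB = 0.5, wV = 30, wG = 0.8, wC = 0.2))
    new("ScoreParams",
        delta = if (is.null(delta)) def$delta else delta,
        wB = if (is.null(wB)) def$wB else wB,
        wV = if (is.null(wV)) def$wV else wV,
        wG = if (is.null(wG)) def$wG else wG,
        wC = if (is.null(wC)) def$wC else wC,
        volumeForm = volumeForm,
        variancePenalty = variancePenalty,
        varianceEps = varianceEps)
}

#' Convert score parameters to/from a plain list
#'
#' Round-trip helpers for serializing a [ScoreParams-class] to a JSON or YAML
#' configuration block using the field names \code{delta}, \code{w_b},
#' \code{w_v}, \code{w_g}, \code{w_c}, \code{volume_form}.
#'
#' @param params a [ScoreParams-class] object.
#' @param x a named list as produced by [scoreParamsToList()] (unknown names
#'   are an error; missing names keep their defaults).
#' @return [scoreParamsToList()] a named list; [scoreParamsFromList()] a
#'   [ScoreParams-class].
#' @export
scoreParamsToList <- function(params) {
    stopifnot(is(params, "ScoreParams"))
    list(delta = params@delta, w_b = params@wB, w_v = params@wV,
         w_g = params@wG, w_c = params@wC, volume_form = params@volumeForm)
}

#' @rdname scoreParamsToList
#' @export
scoreParamsFromList <- function(x) {
    known <- c("delta", "w_b", "w_v", "w_g", "w_c", "volume_form")
    bad <- setdiff(names(x), known)
    if (length(bad))
        stop("unknown score parameter field(s): ", paste(bad, collapse = ", "))
    p <- scoreParams()
    if (!is.null(x$delta)) p@delta <- as.numeric(x$delta)
    if (!is.null(x$w_b)) p@wB <- as.numeric(x$w_b)
    if (!is.null(x$w_v)) p@wV <- as.numeric(x$w_v)
    if (!is.null(x$w_g)) p@wG <- as.numeric(x$w_g)
    if (!is.null(x$w_c)) p@wC <- as.numeric(x$w_c)
    if (!is.null(x$volume_form)) p@volumeForm <- x$volume_form
    validObject(p)
    p
}

.checkIndexSets <- function(matrix, rows, cols, minSize = 1L) {
    if (!is.matrix(matrix) || !is.numeric(matrix))
        stop("'matrix' must be a numeric matrix")
    rows <- as.integer(rows); cols <- as.integer(cols)
    if (length(rows) < minSize || length(cols) < minSize)
        stop("index sets must contain at least ", minSize,
             " row(s) and column(s)")
    if (anyDuplicated(rows) || anyDuplicated(cols))
        stop("index sets must not contain duplicates")
    if (any(rows < 1L) || any(rows > nrow(matrix)))
        stop("row indices out of bounds [1, ", nrow(matrix), "]")
    if (any(cols < 1L) || any(cols > ncol(matrix)))
        stop("column indices out of bounds [1, ", ncol(matrix), "]")
    list(rows = rows, cols = cols)
}

#' Row, column and grand means of a submatrix
#'
#' Computes \eqn{e_{iJ}} (mean of row \eqn{i} over the selected columns),
#' \eqn{e_{Ij}} (mean of column \eqn{j} over the selected rows) and
#' \eqn{e_{IJ}} (grand mean of the submatrix) — the building blocks of the
#' residue \eqn{h_{ij} = e_{ij} - e_{iJ} - e_{Ij} + e_{IJ}}.
#'
#' @param matrix numeric expression matrix (genes x conditions).
#' @param rows,cols integer index vectors selecting the submatrix (1-based,
#'   no duplicates, non-empty).
#' @return A list with components \code{rowMeans} (length \code{|I|}),
#'   \code{colMeans} (length \code{|J|}) and \code{grandMean}.
#' @examples
#' m <- matrix(1:4, 2, 2, byrow = TRUE)
#' submatrixMeans(m, 1:2, 1:2)
#' @export
submatrixMeans <- function(matrix, rows, cols) {
    ix <- .checkIndexSets(matrix, rows, cols)
    sub <- matrix[ix$rows, ix$cols, drop = FALSE]
    list(rowMeans = rowMeans(sub), colMeans = colMeans(sub),
         grandMean = mean(sub))
}

#' Mean squared residue of a submatrix
#'
#' \eqn{H_{IJ} = \frac{1}{|I||J|} \sum_{i \in I, j \in J} h_{ij}^2} with
#' \eqn{h_{ij} = e_{ij} - e_{iJ} - e_{Ij} + e_{IJ}}. Zero exactly when the
#' submatrix follows a perfectly additive model \eqn{e_{ij} = a_i + b_j};
#' identically zero for any single-row or single-column submatrix (which is
#' why scored biclusters require at least 2 rows and 2 columns).
#'
#' @inheritParams submatrixMeans
#' @return numeric(1), \eqn{H_{IJ} \ge 0}.
#' @examples
#' m <- outer(1:4, 1:3, "+") # additive: H = 0
#' meanSquaredResidue(m, 1:4, 1:3)
#' @export
meanSquaredResidue <- function(matrix, rows, cols) {
    ix <- .checkIndexSets(matrix, rows, cols)
    sub <- matrix[ix$rows, ix$cols, drop = FALSE]
    rm <- rowMeans(sub); cm <- colMeans(sub); gm <- mean(sub)
    h <- sub - rm # column-major recycling subtracts rowMeans per row
    h <- sweep(h, 2L, cm - gm)
    mean(h * h)
}

#' Row variance of a submatrix
#'
#' \eqn{V_{IJ} = \frac{1}{|I||J|} \sum_{i \in I, j \in J}
#' (e_{ij} - e_{iJ})^2}: the mean squared deviation of each entry from its
#' row mean. Zero only when every selected row is constant over the selected
#' columns — the "trivial" flat biclusters that the variance term of the
#' score is designed to reject.
#'
#' @inheritParams submatrixMeans
#' @return numeric(1), \eqn{V_{IJ} \ge 0}.
#' @export
rowVariance <- function(matrix, rows, cols) {
    ix <- .checkIndexSets(matrix, rows, cols)
    sub <- matrix[ix$rows, ix$cols, drop = FALSE]
    d <- sub - rowMeans(sub)
    mean(d * d)
}

#' The three score terms
#'
#' The score minimized by all algorithms is
#' \eqn{Score(I, J) = RES + VAR + VOL} where
#' \itemize{
#'   \item \code{residueTerm}: \eqn{RES = H/\delta} if \eqn{H > \delta},
#'     else exactly 1 (the boundary \eqn{H = \delta} falls in the
#'     else-branch);
#'   \item \code{varianceTerm}: \eqn{VAR = w_b / V}, with a large fixed
#'     penalty when \eqn{V} is numerically zero so flat biclusters are
#'     dominated;
#'   \item \code{volumeTerm}: in the default reciprocal form
#'     \eqn{VOL = w_v (w_g/|I| + w_c/|J|)}, strictly decreasing in both
#'     cardinalities so that minimizing the score rewards large biclusters;
#'     the \code{"literal_fraction"} form \eqn{w_v (w_g |I|/N + w_c |J|/M)}
#'     is available for fidelity experiments (see the methods vignette).
#' }
#'
#' @param H mean squared residue (vectorized).
#' @param delta residue cutoff \eqn{\delta > 0}.
#' @return numeric, the term value(s).
#' @examples
#' residueTerm(40, 20) # 2
#' residueTerm(20, 20) # boundary: 1
#' @export
residueTerm <- function(H, delta) {
    stopifnot(delta > 0)
    ifelse(H > delta, H / delta, 1)
}

#' @rdname residueTerm
#' @param V row variance (vectorized).
#' @param wB variance weight \eqn{w_b \ge 0}.
#' @param penalty value returned for \eqn{V \le eps}.
#' @param eps degeneracy threshold.
#' @export
varianceTerm <- function(V, wB, penalty = 1e6, eps = 1e-12) {
    stopifnot(wB >= 0)
    ifelse(V <= eps, penalty, wB / V)
}

#' @rdname residueTerm
#' @param nRows,nCols bicluster cardinalities \eqn{|I|}, \eqn{|J|}.
#' @param N,M full matrix dimensions (used by the literal form only).
#' @param params a [ScoreParams-class] object.
#' @export
volumeTerm <- function(nRows, nCols, N, M, params = scoreParams()) {
    stopifnot(is(params, "ScoreParams"))
    if (params@volumeForm == "reciprocal_cardinality")
        params@wV * (params@wG / nRows + params@wC / nCols)
    else
        params@wV * (params@wG * nRows / N + params@wC * nCols / M)
}

# Fast internal kernel: returns c(score, H, V, volume) for one (rows, cols)
# pair without argument checking or S4 construction. The engine's hot loop.
.scorePair <- function(matrix, rows, cols, params, sentinel = 1e9) {
    nr <- length(rows); nc <- length(cols)
    if (nr < 2L || nc < 2L)
        return(c(sentinel, NA_real_, NA_real_, nr * nc))
    sub <- matrix[rows, cols, drop = FALSE]
    rm <- .rowMeans(sub, nr, nc)
    cm <- .colMeans(sub, nr, nc)
    gm <- sum(sub) / (nr * nc)
    d <- sub - rm
    V <- sum(d * d) / (nr * nc)
    h <- d - rep(cm - gm, each = nr)
    H <- sum(h * h) / (nr * nc)
    RES <- if (H > params@delta) H / params@delta else 1
    VAR <- if (V <= params@varianceEps) params@variancePenalty else params@wB / V
    VOL <- if (params@volumeForm == "reciprocal_cardinality")
        params@wV * (params@wG / nr + params@wC / nc)
    else
        params@wV * (params@wG * nr / nrow(matrix) +
                     params@wC * nc / ncol(matrix))
    c(RES + VAR + VOL, H, V, nr * nc)
}

#' Score a candidate bicluster
#'
#' Evaluates the combined objective \eqn{Score = RES + VAR + VOL} (lower is
#' better) for the submatrix selected by \code{rows} and \code{cols} and
#' returns a [Bicluster-class] caching \eqn{H_{IJ}}, \eqn{V_{IJ}}, the
#' volume and the score.
#'
#' @inheritParams submatrixMeans
#' @param params a [ScoreParams-class] object.
#' @return A [Bicluster-class] object.
#' @examples
#' m <- matrix(runif(100 * 20, 0, 500), 100, 20)
#' scoreBicluster(m, 1:16, 1:9, scoreParams("artificial"))
#' @export
scoreBicluster <- function(matrix, rows, cols, params = scoreParams()) {
    stopifnot(is(params, "ScoreParams"))
    ix <- .checkIndexSets(matrix, rows, cols, minSize = 2L)
    rows <- sort(ix$rows); cols <- sort(ix$cols)
    s <- .scorePair(matrix, rows, cols, params)
    new("Bicluster", rows = rows, cols = cols,
        H = s[2L], V = s[3L], volume = s[4L], score = s[1L])
}

#' @rdname Bicluster-class
#' @export
setMethod("geneIndices", "Bicluster", function(x) x@rows)

#' @rdname Bicluster-class
#' @export
setMethod("conditionIndices", "Bicluster", function(x) x@cols)

#' @rdname Bicluster-class
#' @export
setMethod("residueScore", "Bicluster", function(x) x@H)

#' @rdname Bicluster-class
#' @export
setMethod("varianceScore", "Bicluster", function(x) x@V)

#' @rdname Bicluster-class
#' @export
setMethod("biclusterVolume", "Bicluster", function(x) x@volume)

#' @rdname Bicluster-class
#' @export
setMethod("biclusterScore", "Bicluster", function(x) x@score)

setMethod("show", "Bicluster", function(object) {
    cat(sprintf("Bicluster: %d genes x %d conditions (volume %d)\n",
                length(object@rows), length(object@cols),
                as.integer(object@volume)))
    cat(sprintf("  H (mean squared residue): %.4g\n", object@H))
    cat(sprintf("  V (row variance):         %.4g\n", object@V))
    cat(sprintf("  score:                    %.4g\n", object@score))
})

setMethod("show", "ScoreParams", function(object) {
    cat("ScoreParams\n")
    cat(sprintf("  delta = %g, w_b = %g, w_v = %g, w_g = %g, w_c = %g\n",
                object@delta, object@wB, object@wV, object@wG, object@wC))
    cat(sprintf("  volume form: %s\n", object@volumeForm))
})
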