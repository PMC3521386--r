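#' Read a gene x condition expression matrix from TSV
#'
#' Parses a tab-separated file whose first row holds condition labels and
#' whose first column holds gene identifiers. Cells must be numeric or one
#' of the \code{missingTokens} (matched case-insensitively); missing cells
#' are flagged as \code{NA} and left for [imputeMissingUniform()].
#'
#' @param path path to the TSV file.
#' @param missingTokens character vector of tokens treated as missing
#'   (case-insensitive). Default \code{c("", "NA", "NaN", "null")}.
#' @return A numeric matrix with gene rownames and condition colnames;
#'   missing entries are \code{NA}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tc1\tc2", "g1\t1\t2", "g2\t3\tNA"), tf)
#' m <- readExpressionMatrix(tf)
#' sum(is.na(m)) # 1
#' @export
readExpressionMatrix <- function(path,
                                 missingTokens = c("", "NA", "NaN", "null")) {
    lines <- readLines(path)
    while (length(lines) && !nzchar(trimws(lines[length(lines)])))
        lines <- lines[-length(lines)] # trailing blank lines are harmless
    if (length(lines) < 3L)
        stop("expression matrix needs a header plus at least 2 gene rows: ",
             path)
    fields <- strsplit(sub("\r$", "", lines), "\t", fixed = TRUE)
    header <- fields[[1L]]
    nCol <- length(header)
    if (nCol < 3L)
        stop("expression matrix needs at least 2 condition columns: ", path)
    condIds <- header[-1L]
    widths <- lengths(fields[-1L])
    bad <- which(widths != nCol)
    if (length(bad))
        stop(sprintf(
            "malformed row %d of '%s': %d fields, expected %d",
            bad[1L] + 1L, path, widths[bad[1L]], nCol))
    geneIds <- vapply(fields[-1L], `[[`, character(1), 1L)
    if (anyDuplicated(geneIds))
        stop("duplicate gene identifiers: ",
             paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
    if (anyDuplicated(condIds))
        stop("duplicate condition labels: ",
             paste(unique(condIds[duplicated(condIds)]), collapse = ", "))
    cells <- unlist(lapply(fields[-1L], `[`, -1L), use.names = FALSE)
    cells <- trimws(cells)
    isMissing <- tolower(cells) %in% tolower(missingTokens)
    values <- suppressWarnings(as.numeric(cells))
    badCell <- which(!isMissing & !is.finite(values))
    if (length(badCell)) {
        row <- (badCell[1L] - 1L) %/% (nCol - 1L) + 2L
        stop(sprintf("non-numeric cell '%s' at row %d of '%s'",
                     cells[badCell[1L]], row, path))
    }
    values[isMissing] <- NA_real_
    m <- matrix(values, nrow = length(geneIds), ncol = nCol - 1L,
                byrow = TRUE, dimnames = list(geneIds, condIds))
    m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [readExpressionMatrix()]: writes the matrix with a condition
#' header row and a leading gene-identifier column; \code{NA} entries are
#' written as the literal token \code{"NA"}.
#'
#' @param matrix numeric matrix with rownames and colnames.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(matrix, path) {
    stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
              !is.null(colnames(matrix)))
    df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    invisible(path)
}

#' Impute missing entries with uniform draws
#'
#' Replaces every \code{NA} entry with an independent draw from
#' Uniform(\code{low}, \code{high}), the protocol used for the yeast
#' cell-cycle matrix with bounds \eqn{[0, 600]}. Non-missing entries are
#' untouched and the result is reproducible given \code{seed}.
#'
#' @param matrix numeric matrix, possibly with \code{NA} entries.
#' @param low,high imputation bounds, \code{low < high}.
#' @param seed integer RNG seed.
#' @return The matrix with every entry finite.
#' @export
imputeMissingUniform <- function(matrix, low = 0, high = 600, seed = 1L) {
    stopifnot(is.matrix(matrix), is.numeric(matrix), low < high)
    miss <- which(is.na(matrix))
    if (length(miss)) {
        rng <- .seededRng(seed)
        matrix[miss] <- rng(function() stats::runif(length(miss), low, high))
    }
    matrix
}

# Run `expr()` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All package randomness funnels through this.
.seededRng <- function(seed) {
    seed <- as.integer(seed)
    function(expr) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()))
        } else {
            on.exit(rm(".Random.seed", envir = globalenv()))
        }
        set.seed(seed)
        expr()
    }
}

#' Write and read bicluster result reports
#'
#' \code{writeBiclusterResults} emits a human-readable TSV report (one record
#' per bicluster: gene labels, condition labels, H, V, volume, score — labels
#' only, never numeric indices) together with a machine-readable JSON sidecar
#' at \code{paste0(path, ".json")}. \code{readBiclusterResults} reads the
#' sidecar back into [Bicluster-class] objects, so that
#' \code{read(write(x))} round-trips the index sets and scores.
#'
#' @param biclusters list of [Bicluster-class] objects.
#' @param matrix the expression matrix the biclusters refer to (supplies the
#'   gene/condition labels and bounds-checking).
#' @param path output TSV path; the JSON sidecar goes to
#'   \code{paste0(path, ".json")}.
#' @return \code{writeBiclusterResults}: invisibly, the sidecar path.
#'   \code{readBiclusterResults}: a list of [Bicluster-class].
#' @export
writeBiclusterResults <- function(biclusters, matrix, path) {
    stopifnot(is.list(biclusters), is.matrix(matrix))
    geneIds <- rownames(matrix)
    condIds <- colnames(matrix)
    if (is.null(geneIds)) geneIds <- paste0("g", seq_len(nrow(matrix)))
    if (is.null(condIds)) condIds <- paste0("c", seq_len(ncol(matrix)))
    for (b in biclusters) {
        stopifnot(is(b, "Bicluster"))
        if (any(b@rows > nrow(matrix)) || any(b@cols > ncol(matrix)))
            stop("bicluster index sets exceed matrix bounds")
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("bicluster", "n_genes", "n_conditions", "H", "V",
                     "volume", "score", "genes", "conditions", sep = "\t"),
               con)
    records <- vector("list", length(biclusters))
    for (k in seq_along(biclusters)) {
        b <- biclusters[[k]]
        rows <- geneIds[b@rows]
        cols <- condIds[b@cols]
        writeLines(paste(k, length(rows), length(cols),
                         format(b@H, digits = 10),
                         format(b@V, digits = 10),
                         as.integer(b@volume),
                         format(b@score, digits = 10),
                         paste(rows, collapse = ","),
                         paste(cols, collapse = ","), sep = "\t"), con)
        records[[k]] <- list(rows = rows, cols = cols, H = b@H, V = b@V,
                             volume = b@volume, score = b@score)
    }
    sidecar <- paste0(path, ".json")
    jsonlite::write_json(records, sidecar, auto_unbox = TRUE, digits = NA)
    invisible(sidecar)
}

#' @rdname writeBiclusterResults
#' @export
readBiclusterResults <- function(path, matrix) {
    sidecar <- if (endsWith(path, ".json")) path else paste0(path, ".json")
    records <- jsonlite::read_json(sidecar, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE)
    geneIds <- rownames(matrix)
    condIds <- colnames(matrix)
    lapply(records, function(r) {
        rows <- match(unlist(r$rows), geneIds)
        cols <- match(unlist(r$cols), condIds)
        if (anyNA(rows) || anyNA(cols))
            stop("report labels not found in the supplied matrix")
        new("Bicluster", rows = sort(as.integer(rows)),
            cols = sort(as.integer(cols)),
            H = as.numeric(r$H), V = as.numeric(r$V),
            volume = as.numeric(r$volume), score = as.numeric(r$score))
    })
}
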