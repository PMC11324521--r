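#' Write a simulated dataset as a plain-text fixture directory
#'
#' Emits the 10x-style trio \code{matrix.mtx} (MatrixMarket coordinate
#' integer, features x barcodes), \code{barcodes.tsv} and
#' \code{features.tsv} (one id per line), plus \code{cells.csv}
#' (\code{cell_id,cell_type,condition,sample,pseudotime}),
#' \code{lr_pairs.csv} (\code{ligand,receptor}) and \code{truth.json}.
#' The file set round-trips losslessly through \code{\link{readCounts}} /
#' \code{\link{readFixture}}.
#'
#' @param sce a \code{SingleCellExperiment} from \code{\link{simulateDataset}}
#'   (or any SCE with a counts assay and the same colData columns).
#' @param dir output directory, created if needed.
#' @return Invisibly, the vector of files written.
#' @export
writeFixture <- function(sce, dir) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create directory: ", dir)
    counts <- .getCounts(sce)
    cd <- as.data.frame(colData(sce))

    mtx <- file.path(dir, "matrix.mtx")
    .writeMTXInteger(counts, mtx)
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
    writeLines(rownames(counts), file.path(dir, "features.tsv"))

    cells <- data.frame(cell_id = cd$cell_id, cell_type = cd$cell_type,
                        condition = cd$condition, sample = cd$sample,
                        pseudotime = cd$pseudotime)
    utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE,
                     quote = FALSE)
    lr <- metadata(sce)$lrPairs
    if (is.null(lr))
        lr <- data.frame(ligand = character(), receptor = character())
    utils::write.csv(lr, file.path(dir, "lr_pairs.csv"), row.names = FALSE,
                     quote = FALSE)
    truth <- metadata(sce)$truth
    if (!is.null(truth))
        jsonlite::write_json(truth, file.path(dir, "truth.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv",
                               "cells.csv", "lr_pairs.csv", "truth.json")))
}

# MatrixMarket "coordinate integer general" writer (Matrix::writeMM only
# emits the real typecode; the 10x convention is integer).
.writeMTXInteger <- function(m, path) {
    tm <- methods::as(methods::as(m, "TsparseMatrix"), "generalMatrix")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 sprintf("%d %d %d", nrow(m), ncol(m), length(tm@x))),
               con)
    if (length(tm@x))
        writeLines(sprintf("%d %d %d", tm@i + 1L, tm@j + 1L,
                           as.integer(tm@x)), con)
    invisible(path)
}

#' Read a count matrix from an MTX fixture directory
#'
#' Expects \code{matrix.mtx[.gz]}, \code{barcodes.tsv[.gz]} and
#' \code{features.tsv[.gz]}. Duplicate coordinate entries are summed, per the
#' MatrixMarket convention.
#'
#' @param dir directory holding the three files.
#' @return A sparse \code{dgCMatrix}, genes (features) x cells (barcodes).
#' @export
readCounts <- function(dir) {
    pick <- function(base) {
        for (f in file.path(dir, c(base, paste0(base, ".gz"))))
            if (file.exists(f)) return(f)
        stop("missing file: ", file.path(dir, base))
    }
    m <- Matrix::readMM(pick("matrix.mtx"))
    barcodes <- readLines(pick("barcodes.tsv"))
    features <- readLines(pick("features.tsv"))
    if (nrow(m) != length(features))
        stop(sprintf("features.tsv has %d ids but matrix.mtx has %d rows",
                     length(features), nrow(m)))
    if (ncol(m) != length(barcodes))
        stop(sprintf("barcodes.tsv has %d ids but matrix.mtx has %d columns",
                     length(barcodes), ncol(m)))
    m <- methods::as(m, "CsparseMatrix")   # sums duplicate entries
    dimnames(m) <- list(features, barcodes)
    m
}

#' Read a full fixture directory back into a SingleCellExperiment
#'
#' @param dir directory written by \code{\link{writeFixture}} (the
#'   \code{cells.csv}, \code{lr_pairs.csv} and \code{truth.json} parts are
#'   optional).
#' @return A \code{SingleCellExperiment} mirroring the writer's input.
#' @export
readFixture <- function(dir) {
    counts <- readCounts(dir)
    cellsFile <- file.path(dir, "cells.csv")
    cd <- if (file.exists(cellsFile)) {
        cells <- utils::read.csv(cellsFile, stringsAsFactors = FALSE)
        S4Vectors::DataFrame(cells, row.names = cells$cell_id)
    } else {
        S4Vectors::DataFrame(cell_id = colnames(counts),
                             row.names = colnames(counts))
    }
    sce <- SingleCellExperiment(assays = list(counts = counts),
                                colData = cd[colnames(counts), ,
                                             drop = FALSE])
    lrFile <- file.path(dir, "lr_pairs.csv")
    if (file.exists(lrFile))
        metadata(sce)$lrPairs <- utils::read.csv(lrFile,
                                                 stringsAsFactors = FALSE)
    truthFile <- file.path(dir, "truth.json")
    if (file.exists(truthFile)) {
        tr <- jsonlite::read_json(truthFile, simplifyVector = TRUE)
        if (!is.null(tr$moduleMembership))
            tr$moduleMembership <- unlist(tr$moduleMembership)
        if (!is.null(tr$pseudotime))
            tr$pseudotime <- unlist(tr$pseudotime)
        metadata(sce)$truth <- tr
    }
    sce
}
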