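#' Per-barcode quality-control metrics
#'
#' Computes, for every barcode (cell column), the total UMI count, the number
#' of detected features (genes with count > 0), the percentage of counts from
#' mitochondrial and hemoglobin genes, and the library complexity
#' \code{log10(n_features) / log10(total_counts)}. Complexity is undefined
#' (NA) when total counts < 2 or no feature is detected, which avoids
#' division by log10(1) = 0; such barcodes fail the complexity filter.
#'
#' @param counts genes x cells count matrix (sparse or dense) or an SCE.
#' @param mitoGenes,hemoGenes character vectors of gene ids; ids absent from
#'   the matrix trigger a warning and are ignored.
#' @return A \code{DataFrame} with one row per barcode: \code{total_counts},
#'   \code{n_features}, \code{pct_mito}, \code{pct_hemoglobin},
#'   \code{complexity}.
#' @examples
#' m <- Matrix::sparseMatrix(i = rep(1:100, 2), j = rep(1:2, each = 100),
#'                           x = rep(100, 200),
#'                           dimnames = list(sprintf("g%03d", 1:100),
#'                                           c("b1", "b2")))
#' barcodeMetrics(m)["b1", "complexity"]  # log10(100)/log10(10000) = 0.5
#' @export
barcodeMetrics <- function(counts, mitoGenes = character(),
                           hemoGenes = character()) {
    counts <- .getCounts(counts)
    if (nrow(counts) == 0 || ncol(counts) == 0)
        stop("empty count matrix")
    for (nm in c("mitoGenes", "hemoGenes")) {
        gs <- get(nm)
        miss <- setdiff(gs, rownames(counts))
        if (length(miss))
            warning(length(miss), " ", nm, " id(s) not in the matrix")
    }
    total <- colSums(counts)
    nFeat <- colSums(counts > 0)
    pctOf <- function(gs) {
        gs <- intersect(gs, rownames(counts))
        if (!length(gs)) return(rep(0, ncol(counts)))
        ifelse(total > 0, 100 * colSums(counts[gs, , drop = FALSE]) / total, 0)
    }
    complexity <- ifelse(total >= 2 & nFeat >= 1,
                         log10(nFeat) / log10(total), NA_real_)
    DataFrame(total_counts = as.integer(total),
              n_features = as.integer(nFeat),
              pct_mito = pctOf(mitoGenes),
              pct_hemoglobin = pctOf(hemoGenes),
              complexity = complexity,
              row.names = colnames(counts))
}

#' Filter barcodes on QC metrics
#'
#' A barcode is kept iff total counts >= minUMIs AND detected features >=
#' minFeatures AND mitochondrial percentage < maxPctMito AND hemoglobin
#' percentage < maxPctHemo AND complexity > minComplexity. The percentage and
#' complexity bounds are strict; barcodes with undefined complexity fail.
#'
#' @param metrics output of \code{\link{barcodeMetrics}}.
#' @param thresholds a \code{\link{qcThresholds}} object.
#' @return Character vector of kept barcode ids (possibly empty, with a
#'   message).
#' @export
filterBarcodes <- function(metrics, thresholds = qcThresholds()) {
    keep <- metrics$total_counts >= thresholds@minUMIs &
        metrics$n_features >= thresholds@minFeatures &
        metrics$pct_mito < thresholds@maxPctMito &
        metrics$pct_hemoglobin < thresholds@maxPctHemo &
        !is.na(metrics$complexity) &
        metrics$complexity > thresholds@minComplexity
    kept <- rownames(metrics)[keep]
    if (!length(kept))
        message("no barcodes pass the QC filters")
    kept
}

#' Filter genes on total counts and barcode support
#'
#' A gene is kept iff it has at least \code{geneMinCounts} counts in total,
#' coming from at least \code{geneMinBarcodes} distinct barcodes. Both
#' bounds are inclusive and evaluated on the raw matrix in a single pass.
#'
#' @inheritParams barcodeMetrics
#' @param thresholds a \code{\link{qcThresholds}} object.
#' @return Character vector of kept gene ids.
#' @export
filterGenes <- function(counts, thresholds = qcThresholds()) {
    counts <- .getCounts(counts)
    if (nrow(counts) == 0 || ncol(counts) == 0)
        stop("empty count matrix")
    keep <- rowSums(counts) >= thresholds@geneMinCounts &
        rowSums(counts > 0) >= thresholds@geneMinBarcodes
    rownames(counts)[keep]
}

#' Gene ids matching a prefix
#'
#' Convenience selector for mitochondrial (\code{"mt-"}) or hemoglobin
#' (\code{"Hb"}) gene sets when no explicit list is available.
#'
#' @param counts genes x cells matrix or SCE.
#' @param prefix id prefix, matched case-sensitively at the start.
#' @return Character vector of matching gene ids.
#' @export
genesByPrefix <- function(counts, prefix) {
    g <- rownames(.getCounts(counts))
    g[startsWith(g, prefix)]
}

#' Apply barcode and gene QC to a dataset in one pass
#'
#' Both filters are computed on the raw matrix (single-pass semantics: gene
#' metrics are not re-evaluated after barcode removal, and vice versa), then
#' the surviving submatrix is returned.
#'
#' @param sce SCE or genes x cells count matrix.
#' @param mitoGenes,hemoGenes explicit gene-id sets; defaults select by
#'   prefix via \code{mitoPrefix}/\code{hemoPrefix}.
#' @param mitoPrefix,hemoPrefix prefixes used when no explicit set is given.
#' @param thresholds a \code{\link{qcThresholds}} object.
#' @return The input subset to kept genes x kept barcodes, with the metrics
#'   table attached (SCE: \code{metadata()$qcMetrics}; matrix: attribute).
#' @export
applyQC <- function(sce, mitoGenes = NULL, hemoGenes = NULL,
                    mitoPrefix = "mt-", hemoPrefix = "Hb",
                    thresholds = qcThresholds()) {
    counts <- .getCounts(sce)
    if (is.null(mitoGenes)) mitoGenes <- genesByPrefix(counts, mitoPrefix)
    if (is.null(hemoGenes)) hemoGenes <- genesByPrefix(counts, hemoPrefix)
    metrics <- barcodeMetrics(counts, mitoGenes, hemoGenes)
    cells <- filterBarcodes(metrics, thresholds)
    genes <- filterGenes(counts, thresholds)
    out <- sce[genes, cells]
    if (is(out, "SummarizedExperiment")) {
        metadata(out)$qcMetrics <- metrics
    } else {
        attr(out, "qcMetrics") <- metrics
    }
    out
}
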