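#' Fisher's combination of p-values
#'
#' Combines a vector of (possibly adjusted) p-values with Fisher's method:
#' the statistic \code{-2 * sum(log(p))} is referred to a chi-square
#' distribution with \code{2 * length(p)} degrees of freedom. Zero p-values
#' are clamped to the smallest positive representable value (with a
#' message).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return List with \code{statistic}, \code{df} and \code{p}.
#' @examples
#' fisherCombine(c(0.05, 0.05))$p  # ~0.0175
#' @export
fisherCombine <- function(p) {
    if (!length(p)) stop("empty p-value vector")
    p <- .clampP(p)
    stat <- -2 * sum(log(p))
    list(statistic = stat, df = 2L * length(p),
         p = stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE))
}

#' Aggregate one-vs-many pairwise DGE results
#'
#' For a cluster compared against several others: the per-gene mean log2
#' fold change across comparisons, a Fisher combination of the
#' per-comparison adjusted p-values (the default; set
#' \code{combineAdjusted = FALSE} to combine raw p-values instead), and the
#' number of comparisons whose log2FC exceeds \code{lfcThreshold}.
#'
#' @param results list of \code{\link{nbWaldTest}} results (one per pairwise
#'   comparison). Gene universes are intersected with a warning when they
#'   differ.
#' @param lfcThreshold strict threshold for counting comparisons
#'   (default 2).
#' @param combineAdjusted combine adjusted (\code{pAdj}) rather than raw
#'   p-values.
#' @return \code{DataFrame} with \code{gene}, \code{meanLog2FC},
#'   \code{combinedP}, \code{nAboveThreshold}.
#' @export
aggregateOneVsMany <- function(results, lfcThreshold = 2,
                               combineAdjusted = TRUE) {
    if (!length(results)) stop("at least one pairwise result required")
    universes <- lapply(results, function(r) r$gene)
    genes <- Reduce(intersect, universes)
    if (!all(lengths(universes) == length(genes)))
        warning("gene universes differ across comparisons; intersecting to ",
                length(genes), " genes")
    lfc <- vapply(results, function(r) r[genes, "log2FC"],
                  numeric(length(genes)))
    pcol <- if (combineAdjusted) "pAdj" else "p"
    pm <- vapply(results, function(r) r[genes, pcol],
                 numeric(length(genes)))
    lfc <- matrix(lfc, nrow = length(genes))
    pm <- matrix(pm, nrow = length(genes))
    comb <- apply(pm, 1, function(p) fisherCombine(p)$p)
    DataFrame(gene = genes,
              meanLog2FC = rowMeans(lfc),
              combinedP = comb,
              nAboveThreshold = as.integer(rowSums(lfc > lfcThreshold)),
              row.names = genes)
}

#' Prepare radial-plot quadrant data from per-cell-type condition DGE
#'
#' For each cell type with a control-vs-mutant DGE result, emits two
#' quadrants (one per condition) in which every tested gene appears:
#' in a quadrant, genes upregulated in that condition keep their log2FC and
#' adjusted p, while genes with negative log2FC are clipped to 0 and their
#' adjusted p set to 1.
#'
#' @param results named list (by cell type) of \code{\link{nbWaldTest}}
#'   results with log2FC oriented mutant over control.
#' @param conditions labels for the two quadrants, mutant first.
#' @return data.frame with columns \code{cell_type}, \code{condition},
#'   \code{gene}, \code{log2FC}, \code{pAdj}.
#' @export
radialPlotData <- function(results, conditions = c("cKO", "control")) {
    out <- lapply(names(results), function(ct) {
        r <- results[[ct]]
        quad <- function(lfc, padj, cond) {
            clip <- lfc < 0
            data.frame(cell_type = ct, condition = cond, gene = r$gene,
                       log2FC = ifelse(clip, 0, lfc),
                       pAdj = ifelse(clip, 1, padj))
        }
        rbind(quad(r$log2FC, r$pAdj, conditions[1]),
              quad(-r$log2FC, r$pAdj, conditions[2]))
    })
    do.call(rbind, out)
}

#' Select genes elevated in a cluster of interest
#'
#' Keeps genes meeting all three inclusive thresholds on the one-vs-many
#' aggregation: mean log2FC, combined adjusted p, and expressed fraction in
#' the cluster of interest.
#'
#' @param agg \code{\link{aggregateOneVsMany}} result.
#' @param frac named per-gene expressed fraction in the cluster of interest.
#' @param minLog2FC,maxPAdj,minFrac inclusive thresholds (defaults 1, 0.05,
#'   0.2).
#' @return Character vector of selected gene ids.
#' @export
selectElevatedGenes <- function(agg, frac, minLog2FC = 1, maxPAdj = 0.05,
                                minFrac = 0.2) {
    if (!nrow(agg)) return(character())
    f <- frac[agg$gene]
    f[is.na(f)] <- 0
    agg$gene[agg$meanLog2FC >= minLog2FC & agg$combinedP <= maxPAdj &
             f >= minFrac]
}
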