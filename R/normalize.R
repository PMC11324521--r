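#' Depth-normalize a QC-filtered count matrix
#'
#' Size factors default to each cell's total count divided by the median
#' total count, rescaled to unit geometric mean so expected depth is
#' preserved; normalized values are raw counts divided by the cell's size
#' factor, optionally log1p-transformed. (Pooled deconvolution factors are
#' deliberately not reimplemented; any externally computed positive factors
#' can be supplied instead.)
#'
#' @param counts genes x cells count matrix (sparse or dense) or SCE.
#' @param log apply \code{log1p} after depth scaling.
#' @param sizeFactors optional externally computed per-cell positive factors.
#' @return A \code{\link{NormalizedMatrix}}.
#' @examples
#' m <- matrix(rpois(200, 5), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
#' norm <- normalizeCounts(m)
#' norm
#' @export
normalizeCounts <- function(counts, log = FALSE, sizeFactors = NULL) {
    counts <- .getCounts(counts)
    total <- colSums(counts)
    if (any(total == 0))
        stop("barcode(s) with zero total counts: ",
             paste(utils::head(colnames(counts)[total == 0]), collapse = ", "),
             " (run QC first)")
    if (is.null(sizeFactors)) {
        sf <- total / stats::median(total)
        sf <- sf / exp(mean(log(sf)))
    } else {
        if (any(sizeFactors <= 0)) stop("size factors must be > 0")
        sf <- sizeFactors
    }
    vals <- counts %*% Diagonal(x = 1 / sf)
    dimnames(vals) <- dimnames(counts)
    if (log) vals <- log1p(vals)
    new("NormalizedMatrix", values = vals,
        sizeFactors = stats::setNames(as.numeric(sf), colnames(counts)),
        logTransformed = log)
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log1p-transformed normalized
#' expression (values already on the log scale are used as-is) and returns
#' the top \code{n}; ties are broken lexicographically by gene id so the
#' selection is deterministic.
#'
#' @param norm a \code{\link{NormalizedMatrix}} (or plain matrix of
#'   normalized values).
#' @param n number of genes to select; must be positive and at most the
#'   number of genes.
#' @return Character vector of \code{n} gene ids, most variable first.
#' @export
selectHVG <- function(norm, n) {
    vals <- normValues(norm)
    if (n <= 0) stop("'n' must be positive")
    if (n > nrow(vals)) stop("'n' exceeds the number of genes")
    x <- if (is(norm, "NormalizedMatrix") && norm@logTransformed)
        .asDense(vals) else log1p(.asDense(vals))
    v <- .rowSds(x)^2
    rownames(vals)[order(-v, rownames(vals))][seq_len(n)]
}

#' Scale genes to zero mean and unit variance with an upper cap
#'
#' Per-gene z-scaling of normalized expression across cells (sample sd),
#' followed by capping values at \code{cap} from above only; no lower cap is
#' applied. Genes with zero variance map to all-zero rows.
#'
#' @param norm a \code{\link{NormalizedMatrix}} or matrix.
#' @param cap upper cap on z-values (default 10).
#' @param genes optional subset of gene ids to scale (default all).
#' @return A dense genes x cells matrix of capped z-values.
#' @export
scaleCapped <- function(norm, cap = 10, genes = NULL) {
    x <- .asDense(normValues(norm))
    if (!is.null(genes)) x <- x[genes, , drop = FALSE]
    mu <- rowMeans(x)
    sd <- .rowSds(x)
    z <- (x - mu) / ifelse(sd > 0, sd, 1)
    z[sd == 0, ] <- 0
    pmin(z, cap)
}
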