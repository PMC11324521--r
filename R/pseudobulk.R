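#' Sum raw counts into pseudobulk profiles
#'
#' Aggregates the raw single-cell counts into one column per
#' (group, sample) pair with at least one cell; entries are summed counts,
#' so the grand total of the pseudobulk matrix equals the grand total of the
#' input.
#'
#' @param counts genes x cells raw count matrix or SCE.
#' @param ann per-cell annotation data.frame (taken from colData for an SCE).
#' @param groupKey,sampleKey annotation columns defining groups and samples.
#' @return A \code{SummarizedExperiment} with assay \code{"counts"}
#'   (genes x pseudosamples) and colData columns \code{group} and
#'   \code{sample}.
#' @export
makePseudobulk <- function(counts, ann = NULL, groupKey = "cell_type",
                           sampleKey = "sample") {
    ann <- .getAnnotation(counts, ann)
    counts <- .getCounts(counts)
    if (any(is.na(ann[[groupKey]])) || any(is.na(ann[[sampleKey]])))
        stop("every cell needs '", groupKey, "' and '", sampleKey, "' labels")
    grp <- factor(paste(ann[[groupKey]], ann[[sampleKey]], sep = "|"))
    idx <- split(seq_len(ncol(counts)), grp)
    pb <- vapply(idx, function(i) rowSums(counts[, i, drop = FALSE]),
                 numeric(nrow(counts)))
    rownames(pb) <- rownames(counts)
    parts <- do.call(rbind, strsplit(names(idx), "|", fixed = TRUE))
    SummarizedExperiment(
        assays = list(counts = pb),
        colData = S4Vectors::DataFrame(group = parts[, 1],
                                       sample = parts[, 2],
                                       row.names = names(idx)))
}

# Median-of-ratios size factors (reference = geometric mean over samples,
# using genes positive in all samples).
.medianOfRatios <- function(k) {
    logk <- log(k)
    ref <- rowMeans(logk)
    use <- is.finite(ref)
    if (!any(use))
        stop("no gene is expressed in all samples; cannot compute size factors")
    apply(logk[use, , drop = FALSE], 2,
          function(col) exp(stats::median(col - ref[use])))
}

#' Two-group pseudobulk differential expression (NB Wald test)
#'
#' A plain negative-binomial Wald test on pseudobulk counts:
#' median-of-ratios size factors; gene-wise NB dispersion by the method of
#' moments on normalized counts (floored at 1e-8); a two-group log-link GLM
#' fit by iteratively reweighted least squares with the size factors as
#' offsets; Wald statistic = log fold change / standard error with a
#' two-sided normal p-value; and Benjamini-Hochberg adjustment across tested
#' genes. No dispersion shrinkage or fold-change moderation is applied.
#' Genes that are all-zero across both groups are excluded and reported in
#' the result's metadata.
#'
#' @param pb pseudobulk \code{SummarizedExperiment} from
#'   \code{\link{makePseudobulk}} (or a genes x samples matrix with a
#'   \code{group} factor supplied via \code{groups}).
#' @param groupA,groupB group labels to compare; fold changes are A over B.
#' @param groups optional explicit per-column group labels.
#' @return A \code{DataFrame} with columns \code{gene}, \code{baseMean},
#'   \code{log2FC}, \code{se}, \code{stat}, \code{p}, \code{pAdj}; excluded
#'   all-zero genes are listed in \code{metadata()$excluded}.
#' @export
nbWaldTest <- function(pb, groupA, groupB, groups = NULL) {
    if (is(pb, "SummarizedExperiment")) {
        k <- assay(pb, "counts")
        if (is.null(groups)) groups <- colData(pb)$group
    } else k <- pb
    if (is.null(groups)) stop("group labels required")
    selA <- which(groups == groupA)
    selB <- which(groups == groupB)
    if (!length(selA) || !length(selB))
        stop("both groups need at least one sample")
    if (length(selA) < 2 || length(selB) < 2)
        warning("fewer than 2 samples in a group; dispersion estimates are ",
                "unreliable")
    k <- as.matrix(k[, c(selA, selB), drop = FALSE])
    x <- rep(c(1, 0), c(length(selA), length(selB)))
    nonzero <- rowSums(k) > 0
    excluded <- rownames(k)[!nonzero]
    k <- k[nonzero, , drop = FALSE]

    sf <- .medianOfRatios(k)
    q <- sweep(k, 2, sf, "/")

    ## method-of-moments dispersion (alpha = 1/theta), pooled within groups
    nA <- sum(x == 1); nB <- sum(x == 0)
    muA <- rowMeans(q[, x == 1, drop = FALSE])
    muB <- rowMeans(q[, x == 0, drop = FALSE])
    ssA <- rowSums((q[, x == 1, drop = FALSE] - muA)^2)
    ssB <- rowSums((q[, x == 0, drop = FALSE] - muB)^2)
    df <- max(nA - 1, 0) + max(nB - 1, 0)
    s2 <- if (df > 0) (ssA + ssB) / df else rep(NA_real_, nrow(q))
    muBar <- rowMeans(q)
    alpha <- pmax((s2 - muBar) / muBar^2, 1e-8)
    alpha[!is.finite(alpha)] <- 1e-8

    fit <- .nbGLM2(k, x, log(sf), alpha)
    log2FC <- fit$beta / log(2)
    se2 <- fit$se / log(2)
    stat <- log2FC / se2
    p <- 2 * stats::pnorm(-abs(stat))
    res <- DataFrame(gene = rownames(k),
                     baseMean = muBar,
                     log2FC = log2FC,
                     se = se2,
                     stat = stat,
                     p = p,
                     pAdj = stats::p.adjust(p, method = "BH"),
                     row.names = rownames(k))
    metadata(res)$excluded <- excluded
    metadata(res)$sizeFactors <- sf
    metadata(res)$comparison <- c(groupA, groupB)
    res
}

# Vector-of-genes NB GLM with design [1, x], log link, offsets o, known
# gene-wise dispersion alpha. Returns natural-log LFC (beta) and its SE.
.nbGLM2 <- function(k, x, o, alpha, maxit = 50L, tol = 1e-10) {
    G <- nrow(k); n <- ncol(k)
    pseudo <- 0.5
    muA0 <- rowMeans(sweep(k[, x == 1, drop = FALSE] + pseudo, 2,
                           exp(o)[x == 1], "/"))
    muB0 <- rowMeans(sweep(k[, x == 0, drop = FALSE] + pseudo, 2,
                           exp(o)[x == 0], "/"))
    b0 <- log(muB0)
    b1 <- log(muA0) - log(muB0)
    X1 <- rep(1, n)
    for (it in seq_len(maxit)) {
        eta <- outer(b0, rep(1, n)) + outer(b1, x) +
            matrix(o, G, n, byrow = TRUE)
        mu <- exp(eta)
        w <- mu / (1 + alpha * mu)
        z <- (eta - matrix(o, G, n, byrow = TRUE)) + (k - mu) / mu
        ## closed-form 2x2 weighted LS per gene
        s11 <- rowSums(w)
        s1x <- w %*% x
        sxx <- w %*% (x * x)
        s1z <- rowSums(w * z)
        sxz <- rowSums(w * z * rep(x, each = G))
        det <- s11 * sxx - s1x^2
        nb0 <- (sxx * s1z - s1x * sxz) / det
        nb1 <- (s11 * sxz - s1x * s1z) / det
        delta <- max(abs(nb0 - b0), abs(nb1 - b1), na.rm = TRUE)
        b0 <- as.numeric(nb0); b1 <- as.numeric(nb1)
        if (delta < tol) break
    }
    eta <- outer(b0, rep(1, n)) + outer(b1, x) + matrix(o, G, n, byrow = TRUE)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    s11 <- rowSums(w)
    s1x <- as.numeric(w %*% x)
    sxx <- as.numeric(w %*% (x * x))
    det <- s11 * sxx - s1x^2
    list(beta = b1, se = sqrt(s11 / det))
}

#' Fraction of cells expressing each gene, per group
#'
#' @param counts genes x cells matrix or SCE.
#' @param ann per-cell annotation (colData for an SCE).
#' @param groupKey annotation column defining the groups.
#' @return genes x groups matrix of fractions of cells with count > 0.
#' @export
fracExpressed <- function(counts, ann = NULL, groupKey = "condition") {
    ann <- .getAnnotation(counts, ann)
    counts <- .getCounts(counts)
    g <- factor(ann[[groupKey]])
    idx <- split(seq_len(ncol(counts)), g)
    out <- vapply(idx,
                  function(i) rowMeans(counts[, i, drop = FALSE] > 0),
                  numeric(nrow(counts)))
    rownames(out) <- rownames(counts)
    out
}

#' Genes expressed above a fraction threshold in at least one group
#'
#' Implements the "expressed in at least \code{minFrac} of cells of the
#' respective group in either condition" filter: a gene is kept when its
#' expressed fraction reaches the threshold in any column of \code{frac}.
#'
#' @param frac genes x groups fraction matrix from
#'   \code{\link{fracExpressed}}.
#' @param minFrac inclusive threshold (default 0.2).
#' @return Character vector of kept gene ids.
#' @export
expressedGenes <- function(frac, minFrac = 0.2) {
    rownames(frac)[apply(frac >= minFrac, 1, any)]
}
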