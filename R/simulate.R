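#' Simulate a synthetic scRNA-seq dataset with planted ground truth
#'
#' Draws a negative-binomial cell x gene count matrix with per-cell-type gene
#' means, log-normal per-cell library-size variation, two conditions, planted
#' ligand/receptor fold changes in designated sender and receiver cell types,
#' and (optionally) a pseudotime lineage whose gene modules follow configured
#' temporal profiles. Counts for cell c and gene g are drawn as
#' NB(mean = s_c * mu[g, type(c), condition(c), t(c)], size = theta) with s_c
#' log-normal and normalized to unit mean.
#'
#' Planted ligand/receptor genes are given a dedicated baseline mean and
#' dispersion in their sender/receiver type (they emulate robustly expressed
#' signaling genes); the configured fold factors multiply the second
#' (mutant) condition's mean. The ground truth per planted interaction is
#' \code{(log2(ligandFold) + log2(receptorFold))/2}.
#'
#' @param config a \code{\link{simulationConfig}} object.
#' @return A \code{SingleCellExperiment} with assay \code{"counts"}
#'   (sparse genes x cells), colData columns \code{cell_id},
#'   \code{cell_type}, \code{condition}, \code{sample}, \code{pseudotime}
#'   (NA outside the lineage), and \code{metadata()} entries \code{truth}
#'   (list: \code{lriDiff}, \code{moduleMembership}, \code{pseudotime}),
#'   \code{lrPairs} (data.frame ligand/receptor including background pairs)
#'   and \code{config}.
#' @examples
#' cfg <- simulationConfig(nCellTypes = 2, cellsPerType = 30, nGenes = 60,
#'                         nBackgroundPairs = 5, seed = 7)
#' sce <- simulateDataset(cfg)
#' sce
#' @export
simulateDataset <- function(config) {
    validObject(config)
    set.seed(config@seed)
    nT <- config@nCellTypes
    nG <- config@nGenes
    types <- paste0("type", seq_len(nT))
    genes <- sprintf("gene%04d", seq_len(nG))
    conds <- config@conditions
    pi <- config@plantedInteractions

    if (nrow(pi)) {
        miss <- setdiff(c(pi$ligand, pi$receptor), genes)
        if (length(miss))
            stop("planted genes not in gene universe: ",
                 paste(miss, collapse = ", "))
        if (!all(c(pi$sender, pi$receiver) %in% types))
            stop("planted sender/receiver types must be among ",
                 paste(types, collapse = ", "))
    }

    ## baseline gene means and per-type multipliers (log-normal, mean-centred)
    baseMu <- config@baselineMean *
        exp(stats::rnorm(nG, -config@geneSigma^2 / 2, config@geneSigma))
    typeMult <- matrix(
        exp(stats::rnorm(nG * nT, -config@typeSigma^2 / 2, config@typeSigma)),
        nG, nT, dimnames = list(genes, types))
    muType <- baseMu * typeMult           # genes x types

    ## planted LR genes: high, type-specific expression
    size <- rep(config@dispersion, nG)
    names(size) <- genes
    if (nrow(pi)) {
        for (i in seq_len(nrow(pi))) {
            muType[pi$ligand[i], pi$sender[i]] <- config@plantedMean
            muType[pi$receptor[i], pi$receiver[i]] <- config@plantedMean
        }
        size[c(pi$ligand, pi$receptor)] <- config@plantedDispersion
    }

    ## per-condition mean arrays; folds multiply the second condition
    muArr <- array(muType, dim = c(nG, nT, 2),
                   dimnames = list(genes, types, conds))
    if (nrow(pi)) {
        for (i in seq_len(nrow(pi))) {
            muArr[pi$ligand[i], pi$sender[i], 2] <-
                muArr[pi$ligand[i], pi$sender[i], 2] * pi$ligandFold[i]
            muArr[pi$receptor[i], pi$receiver[i], 2] <-
                muArr[pi$receptor[i], pi$receiver[i], 2] * pi$receptorFold[i]
        }
    }

    ## cell layout
    nPer <- config@cellsPerType
    cellType <- rep(rep(types, nPer), 2)
    condition <- rep(conds, each = sum(nPer))
    nC <- length(cellType)
    cellId <- sprintf("cell%05d", seq_len(nC))
    sampleId <- paste0(condition, "_s",
                       sample.int(config@samplesPerCondition, nC,
                                  replace = TRUE))

    ## per-cell mean matrix
    ci <- match(cellType, types)
    ki <- match(condition, conds)
    mu <- matrix(0, nG, nC, dimnames = list(genes, cellId))
    for (k in 1:2) {
        sel <- which(ki == k)
        mu[, sel] <- muArr[, ci[sel], k]
    }

    ## trajectory: lineage cells get pseudotime, module genes follow profiles
    traj <- config@trajectory
    pt <- rep(NA_real_, nC)
    moduleMembership <- character(0)
    if (length(traj)) {
        lin <- which(cellType %in% traj$cellTypes)
        if (!length(lin))
            stop("trajectory 'cellTypes' matches no simulated cells")
        pt[lin] <- stats::runif(length(lin))
        amp <- if (is.null(traj$amplitude)) 8 else traj$amplitude
        mods <- traj$modules
        mm <- character()
        for (j in seq_along(mods)) {
            g <- mods[[j]]$genes
            if (is.numeric(g)) g <- genes[g]
            if (!all(g %in% genes))
                stop("trajectory module genes outside gene universe")
            f <- .temporalProfile(pt[lin], mods[[j]]$shape)
            mu[g, lin] <- config@baselineMean *
                rep(0.5 + (amp - 0.5) * f, each = length(g))
            mm[g] <- if (is.null(names(mods)[j]) || names(mods)[j] == "")
                paste0("program", j) else names(mods)[j]
        }
        moduleMembership <- mm
    }

    ## library-size factors, unit mean
    s <- exp(stats::rnorm(nC, 0, config@libsizeSigma))
    s <- s / mean(s)

    counts <- matrix(
        stats::rnbinom(nG * nC,
                       mu = mu * rep(s, each = nG),
                       size = rep(size, nC)),
        nG, nC, dimnames = list(genes, cellId))
    counts <- methods::as(counts, "CsparseMatrix")

    ## ligand-receptor pair table: planted + background null pairs
    lrPairs <- data.frame(ligand = character(), receptor = character(),
                          stringsAsFactors = FALSE)
    if (nrow(pi))
        lrPairs <- data.frame(ligand = pi$ligand, receptor = pi$receptor,
                              stringsAsFactors = FALSE)
    nBg <- config@nBackgroundPairs
    if (nBg > 0) {
        pool <- setdiff(genes, c(pi$ligand, pi$receptor,
                                 names(moduleMembership)))
        if (length(pool) < 2 * nBg)
            stop("not enough non-planted genes for ", nBg,
                 " background pairs")
        bg <- matrix(sample(pool, 2 * nBg), ncol = 2)
        lrPairs <- rbind(lrPairs,
                         data.frame(ligand = bg[, 1], receptor = bg[, 2],
                                    stringsAsFactors = FALSE))
    }

    truth <- list(
        lriDiff = if (nrow(pi)) data.frame(
            ligand = pi$ligand, receptor = pi$receptor,
            sender = pi$sender, receiver = pi$receiver,
            trueDiff = (log2(pi$ligandFold) + log2(pi$receptorFold)) / 2,
            stringsAsFactors = FALSE) else NULL,
        moduleMembership = moduleMembership,
        pseudotime = stats::setNames(pt, cellId)[!is.na(pt)])

    sce <- SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(
            cell_id = cellId, cell_type = cellType, condition = condition,
            sample = sampleId, pseudotime = pt, row.names = cellId))
    metadata(sce)$truth <- truth
    metadata(sce)$lrPairs <- lrPairs
    metadata(sce)$config <- config
    sce
}

# Temporal profile shapes on pseudotime t in [0,1], values in [0,1].
.temporalProfile <- function(t, shape) {
    switch(shape,
        sigmoid_up = stats::plogis((t - 0.5) * 12),
        sigmoid_down = stats::plogis(-(t - 0.5) * 12),
        bump = exp(-(t - 0.5)^2 / (2 * 0.15^2)),
        flat = rep(1, length(t)),
        stop("unknown profile shape: ", shape))
}
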