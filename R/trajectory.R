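#' Bin cells into equal-count pseudotime bins
#'
#' Cells are sorted by (pseudotime, cell id) — ties broken by id — and split
#' into \code{nBins} bins of equal cell numbers; with n = q * nBins + r
#' cells, the first r bins receive q + 1 cells. Bin membership therefore
#' depends only on the ordering, so it is invariant to strictly monotone
#' transforms of pseudotime.
#'
#' @param pseudotime named numeric vector (names = cell ids) or unnamed with
#'   \code{cellIds} supplied; all values must be finite.
#' @param nBins number of bins (default 21).
#' @param cellIds cell ids when \code{pseudotime} is unnamed.
#' @return Named integer vector of bin indices in 1..nBins, in the input
#'   cell order.
#' @export
binPseudotime <- function(pseudotime, nBins = 21, cellIds = NULL) {
    if (is.null(cellIds)) cellIds <- names(pseudotime)
    if (is.null(cellIds)) stop("cell ids required (names or 'cellIds')")
    if (any(!is.finite(pseudotime)))
        stop("pseudotime must be finite for every cell")
    n <- length(pseudotime)
    if (n < nBins)
        stop(sprintf("%d cells cannot fill %d bins", n, nBins))
    ord <- order(pseudotime, cellIds)
    q <- n %/% nBins; r <- n %% nBins
    sizes <- q + (seq_len(nBins) <= r)
    bins <- integer(n)
    bins[ord] <- rep(seq_len(nBins), sizes)
    stats::setNames(bins, cellIds)
}

#' Per-bin mean expression profiles, z-scaled per gene
#'
#' Computes each gene's arithmetic mean normalized expression per pseudotime
#' bin, then z-scales every gene's profile across the bins (zero mean, unit
#' sd). Genes whose per-bin profile has zero variance are dropped and
#' reported via \code{attr(, "dropped")}.
#'
#' @param norm \code{\link{NormalizedMatrix}} or genes x cells matrix
#'   covering the binned cells.
#' @param bins named bin assignment from \code{\link{binPseudotime}}.
#' @param genes genes to profile (e.g. top highly variable genes); default
#'   all.
#' @return genes x bins matrix of z-scaled profiles.
#' @export
binProfiles <- function(norm, bins, genes = NULL) {
    vals <- normValues(norm)
    if (is.null(genes)) genes <- rownames(vals)
    X <- .asDense(vals[genes, names(bins), drop = FALSE])
    nBins <- max(bins)
    P <- vapply(seq_len(nBins),
                function(b) rowMeans(X[, bins == b, drop = FALSE]),
                numeric(length(genes)))
    rownames(P) <- genes
    colnames(P) <- paste0("bin", seq_len(nBins))
    sd <- .rowSds(P)
    dropped <- genes[sd == 0]
    if (length(dropped))
        message(length(dropped), " constant gene profile(s) dropped")
    P <- P[sd > 0, , drop = FALSE]
    Z <- (P - rowMeans(P)) / .rowSds(P)
    attr(Z, "dropped") <- dropped
    Z
}

#' Thresholded gene-gene correlation network
#'
#' Pearson correlation between gene bin-profiles; gene pairs with r strictly
#' above \code{rMin} become undirected edges weighted by r. All profiled
#' genes appear as vertices (possibly isolated); there are no self-edges.
#'
#' @param profiles genes x bins matrix from \code{\link{binProfiles}}.
#' @param rMin strict correlation threshold (default 0.5; r = 0.5 exactly
#'   yields no edge).
#' @return An \code{igraph} graph with edge attribute \code{weight}.
#' @export
correlationGraph <- function(profiles, rMin = 0.5) {
    if (nrow(profiles) < 2) stop("at least 2 genes required")
    C <- stats::cor(t(profiles))
    C[!upper.tri(C)] <- NA
    sel <- which(C > rMin, arr.ind = TRUE)
    g <- igraph::make_empty_graph(n = nrow(profiles), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = rownames(profiles))
    if (nrow(sel))
        g <- igraph::add_edges(g, t(sel), weight = C[sel])
    g
}

#' Gene modules by Leiden clustering of the correlation network
#'
#' Weighted Leiden community detection (modularity objective) at the given
#' resolution. Genes in singleton communities and isolated vertices are
#' assigned module \code{"unclustered"}; remaining modules are labeled M1,
#' M2, ... in decreasing size order. The partition is deterministic for a
#' fixed seed.
#'
#' @param graph graph from \code{\link{correlationGraph}}.
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed RNG seed.
#' @param nIterations Leiden iterations (default 10).
#' @return data.frame with columns \code{gene} and \code{module}.
#' @export
leidenModules <- function(graph, resolution = 1, seed = 1,
                          nIterations = 10) {
    genes <- igraph::V(graph)$name
    if (igraph::ecount(graph) == 0) {
        warning("empty graph; all genes unclustered")
        return(data.frame(gene = genes, module = "unclustered",
                          stringsAsFactors = FALSE))
    }
    set.seed(seed)
    cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                 resolution = resolution,
                                 weights = igraph::E(graph)$weight,
                                 n_iterations = nIterations)
    memb <- igraph::membership(cl)
    sizes <- table(memb)
    real <- names(sizes)[sizes > 1]
    ord <- real[order(-sizes[real], as.integer(real))]
    label <- stats::setNames(rep("unclustered", length(sizes)), names(sizes))
    label[ord] <- paste0("M", seq_along(ord))
    data.frame(gene = genes, module = unname(label[as.character(memb)]),
               stringsAsFactors = FALSE)
}

#' Per-module per-bin summary profiles with confidence bands
#'
#' For each module and bin: the mean z-scaled profile across member genes
#' with a 95\% confidence band, mean +/- 1.96 * sd / sqrt(m) over the m
#' members. Single-gene modules get a zero-width band (flagged by
#' \code{degenerate}).
#'
#' @param modules data.frame from \code{\link{leidenModules}}.
#' @param profiles genes x bins matrix from \code{\link{binProfiles}}.
#' @return data.frame with \code{module}, \code{bin}, \code{mean},
#'   \code{ciLo}, \code{ciHi}, \code{nGenes}, \code{degenerate}.
#' @export
moduleSummaries <- function(modules, profiles) {
    mods <- setdiff(unique(modules$module), "unclustered")
    out <- lapply(mods, function(m) {
        g <- intersect(modules$gene[modules$module == m], rownames(profiles))
        P <- profiles[g, , drop = FALSE]
        mu <- colMeans(P)
        half <- if (length(g) > 1)
            1.96 * apply(P, 2, stats::sd) / sqrt(length(g)) else 0
        data.frame(module = m, bin = seq_len(ncol(P)), mean = mu,
                   ciLo = mu - half, ciHi = mu + half,
                   nGenes = length(g), degenerate = length(g) < 2,
                   row.names = NULL)
    })
    do.call(rbind, out)
}

#' Per-gene per-bin averaged normalized expression with confidence bands
#'
#' The marker-gene view along the trajectory: for each requested gene and
#' bin, the mean normalized expression across the bin's cells with a 95\%
#' confidence band computed across those cells.
#'
#' @param norm \code{\link{NormalizedMatrix}} or matrix.
#' @param bins bin assignment from \code{\link{binPseudotime}}.
#' @param genes genes to summarize.
#' @return data.frame with \code{gene}, \code{bin}, \code{mean},
#'   \code{ciLo}, \code{ciHi}.
#' @export
binAverages <- function(norm, bins, genes) {
    vals <- normValues(norm)
    X <- .asDense(vals[genes, names(bins), drop = FALSE])
    out <- lapply(seq_len(max(bins)), function(b) {
        xb <- X[, bins == b, drop = FALSE]
        mu <- rowMeans(xb)
        half <- 1.96 * apply(xb, 1, stats::sd) / sqrt(ncol(xb))
        data.frame(gene = genes, bin = b, mean = mu, ciLo = mu - half,
                   ciHi = mu + half, row.names = NULL)
    })
    do.call(rbind, out)
}
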