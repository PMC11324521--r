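#' Load and filter a ligand-receptor pair database
#'
#' Canonicalizes a two-column ligand/receptor table the way a consensus
#' resource is consumed: reversed duplicates keep only the first-seen
#' orientation (bidirectional annotations are thereby excluded), pairs whose
#' ligand or receptor is absent from the expression matrix are dropped with
#' a warning, and pairs are dropped when either gene is expressed in fewer
#' than \code{minFrac} of all analyzed cells.
#'
#' @param pairs data.frame with columns \code{ligand} and \code{receptor}
#'   (or a path to a delimited file with that header).
#' @param norm \code{\link{NormalizedMatrix}} (or genes x cells matrix) of
#'   the analyzed cells.
#' @param minFrac minimum expressed fraction, strict lower bound excluded
#'   (default 0.10; genes in < 10\% of cells are removed).
#' @return data.frame with columns \code{ligand}, \code{receptor}.
#' @export
loadLRPairs <- function(pairs, norm, minFrac = 0.10) {
    if (is.character(pairs) && length(pairs) == 1L)
        pairs <- utils::read.csv(pairs, stringsAsFactors = FALSE)
    if (!all(c("ligand", "receptor") %in% names(pairs)))
        stop("pair table needs 'ligand' and 'receptor' columns")
    vals <- normValues(norm)

    ## exact duplicates, then reversed duplicates (keep first orientation)
    key <- paste(pairs$ligand, pairs$receptor, sep = "\r")
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    key <- paste(pairs$ligand, pairs$receptor, sep = "\r")
    rkey <- paste(pairs$receptor, pairs$ligand, sep = "\r")
    drop <- logical(nrow(pairs))
    seen <- character(0)
    for (i in seq_len(nrow(pairs))) {
        if (rkey[i] %in% seen) drop[i] <- TRUE else seen <- c(seen, key[i])
    }
    pairs <- pairs[!drop, , drop = FALSE]

    present <- pairs$ligand %in% rownames(vals) &
        pairs$receptor %in% rownames(vals)
    if (any(!present)) {
        warning(sum(!present), " pair(s) dropped: gene(s) absent from the ",
                "matrix")
        pairs <- pairs[present, , drop = FALSE]
    }
    genes <- unique(c(pairs$ligand, pairs$receptor))
    frac <- rowMeans(vals[genes, , drop = FALSE] > 0)
    ok <- frac[pairs$ligand] >= minFrac & frac[pairs$receptor] >= minFrac
    ok[is.na(ok)] <- FALSE
    pairs <- pairs[ok, , drop = FALSE]
    if (!nrow(pairs))
        stop("no ligand-receptor pairs survive the expression filter")
    rownames(pairs) <- NULL
    pairs[c("ligand", "receptor")]
}

#' Mean expression per gene, cell type and condition
#'
#' Arithmetic means of (non-log) normalized expression over each cell
#' type's cells within each condition, for the requested genes.
#'
#' @param norm \code{\link{NormalizedMatrix}} or genes x cells matrix.
#' @param ann per-cell annotation with \code{cell_type} and \code{condition}
#'   columns (colData for an SCE passed as \code{norm}).
#' @param genes gene ids to compute means for (default: all).
#' @param typeKey,conditionKey annotation column names.
#' @return A 3-d array genes x types x conditions. Absent (type, condition)
#'   combinations hold NA and downstream interactions involving them are
#'   skipped with a warning.
#' @export
groupMeans <- function(norm, ann, genes = NULL, typeKey = "cell_type",
                       conditionKey = "condition") {
    vals <- normValues(norm)
    if (is.null(genes)) genes <- rownames(vals)
    X <- .asDense(vals[genes, , drop = FALSE])
    type <- factor(ann[[typeKey]])
    ## condition levels in order of first appearance: the reference
    ## (control) condition is conventionally listed first in the annotation
    cond <- factor(ann[[conditionKey]],
                   levels = unique(as.character(ann[[conditionKey]])))
    if (any(is.na(type)) || any(is.na(cond)))
        stop("every cell needs a cell type and a condition")
    out <- array(NA_real_,
                 dim = c(length(genes), nlevels(type), nlevels(cond)),
                 dimnames = list(genes, levels(type), levels(cond)))
    for (k in seq_len(nlevels(cond))) {
        for (t in seq_len(nlevels(type))) {
            sel <- which(as.integer(type) == t & as.integer(cond) == k)
            if (length(sel))
                out[, t, k] <- rowMeans(X[, sel, drop = FALSE])
        }
    }
    out
}

# Record layout shared by score and permutation functions: one row per
# (sender, receiver, pair). Index matrices address a genes x (type x cond)
# means matrix stored column-major as [gene, type + (cond-1)*nTypes].
.lriRecords <- function(means, db) {
    genes <- dimnames(means)[[1]]
    types <- dimnames(means)[[2]]
    conds <- dimnames(means)[[3]]
    rec <- expand.grid(pair = seq_len(nrow(db)),
                       sender = types, receiver = types,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rec$ligand <- db$ligand[rec$pair]
    rec$receptor <- db$receptor[rec$pair]
    nG <- length(genes); nT <- length(types)
    colIdx <- function(typeName, condIdx)
        match(typeName, types) + (condIdx - 1L) * nT
    idx <- list()
    for (k in seq_along(conds)) {
        idx[[conds[k]]] <- list(
            lig = (colIdx(rec$sender, k) - 1L) * nG + match(rec$ligand, genes),
            rec = (colIdx(rec$receiver, k) - 1L) * nG +
                match(rec$receptor, genes))
    }
    list(rec = rec, idx = idx, conds = conds)
}

#' Product-based ligand-receptor interaction scores
#'
#' One record per (sender type, receiver type, ligand-receptor pair,
#' condition): the sender supplies the ligand mean (Lmean), the receiver the
#' receptor mean (Rmean), and the interaction score is their product.
#' Self-pairings (sender = receiver) are included; the score is directional,
#' so swapping sender and receiver changes it unless the means coincide.
#'
#' @param means array from \code{\link{groupMeans}} covering all database
#'   genes.
#' @param db data.frame of ligand/receptor pairs from
#'   \code{\link{loadLRPairs}}.
#' @return \code{DataFrame} with \code{sender}, \code{receiver},
#'   \code{ligand}, \code{receptor}, \code{condition}, \code{lmean},
#'   \code{rmean}, \code{score}.
#' @export
lriScores <- function(means, db) {
    lay <- .lriRecords(means, db)
    M <- matrix(means, nrow = dim(means)[1])
    out <- lapply(seq_along(lay$conds), function(k) {
        id <- lay$idx[[k]]
        lm <- M[id$lig]; rmn <- M[id$rec]
        DataFrame(sender = lay$rec$sender, receiver = lay$rec$receiver,
                  ligand = lay$rec$ligand, receptor = lay$rec$receptor,
                  condition = lay$conds[k],
                  lmean = lm, rmean = rmn, score = lm * rmn)
    })
    res <- do.call(rbind, out)
    skip <- is.na(res$score)
    if (any(skip)) {
        warning(sum(skip), " interaction record(s) skipped: empty ",
                "(type, condition) group")
        res <- res[!skip, ]
    }
    res
}

#' Condition-differential communication scores (LRIDiffScore)
#'
#' For each (sender, receiver, pair), the mean of the log2 ratios
#' (mutant over control) of the ligand and receptor means:
#' \code{(log2((Lmut+e)/(Lctl+e)) + log2((Rmut+e)/(Rctl+e))) / 2},
#' computed as a difference of log2 terms so the score negates exactly under
#' condition swap. With \code{epsilon = 0} a record containing a zero mean
#' is flagged undefined (NA score, \code{undefined = TRUE}) rather than
#' dropped.
#'
#' @param means array from \code{\link{groupMeans}} with both conditions.
#' @param db ligand-receptor pair table.
#' @param conditions length-2 vector: reference (control) first, mutant
#'   second. Defaults to the array's condition order.
#' @param epsilon stabilizer added to each mean inside the ratios
#'   (default 1e-9).
#' @return \code{DataFrame} with \code{sender}, \code{receiver},
#'   \code{ligand}, \code{receptor}, the four means, \code{score} and
#'   \code{undefined}.
#' @export
lriDiffScores <- function(means, db, conditions = NULL, epsilon = 1e-9) {
    if (is.null(conditions)) conditions <- dimnames(means)[[3]][1:2]
    stopifnot(length(conditions) == 2,
              all(conditions %in% dimnames(means)[[3]]))
    lay <- .lriRecords(means, db)
    M <- matrix(means, nrow = dim(means)[1])
    iC <- lay$idx[[conditions[1]]]   # control
    iK <- lay$idx[[conditions[2]]]   # mutant
    lC <- M[iC$lig]; rC <- M[iC$rec]
    lK <- M[iK$lig]; rK <- M[iK$rec]
    ## grouped as (ligand term) + (receptor term) so a condition swap
    ## negates each difference, hence the score, exactly in floating point
    score <- ((log2(lK + epsilon) - log2(lC + epsilon)) +
              (log2(rK + epsilon) - log2(rC + epsilon))) / 2
    undefined <- epsilon == 0 & (lC == 0 | rC == 0 | lK == 0 | rK == 0)
    undefined[is.na(undefined)] <- FALSE
    score[undefined] <- NA_real_
    res <- DataFrame(sender = lay$rec$sender, receiver = lay$rec$receiver,
                     ligand = lay$rec$ligand, receptor = lay$rec$receptor,
                     lmeanControl = lC, rmeanControl = rC,
                     lmeanMutant = lK, rmeanMutant = rK,
                     score = score, undefined = undefined)
    skip <- is.na(lC) | is.na(rC) | is.na(lK) | is.na(rK)
    if (any(skip)) {
        warning(sum(skip), " diff record(s) skipped: empty (type, ",
                "condition) group")
        res <- res[!skip, ]
    }
    res
}

#' Filter for significant condition-differential interactions
#'
#' Keeps diff records whose interaction score is significant (adjusted p of
#' the LRI score <= \code{maxPAdj}) in at least one condition, whose diff
#' score's adjusted p is <= \code{maxPAdj}, and whose |diff score| >=
#' \code{minAbsDiff} (or signed diff >= \code{minAbsDiff} when
#' \code{directional = TRUE}).
#'
#' @param lri \code{\link{lriPermTest}} result (records with \code{pAdj} per
#'   condition).
#' @param diff \code{\link{lriDiffPermTest}} result.
#' @param maxPAdj significance threshold (default 0.05).
#' @param minAbsDiff minimum |diff score| (default 1).
#' @param directional require positive diff >= \code{minAbsDiff} instead of
#'   the absolute bound.
#' @return The filtered subset of \code{diff}.
#' @export
significantInteractions <- function(lri, diff, maxPAdj = 0.05,
                                    minAbsDiff = 1, directional = FALSE) {
    if (!nrow(lri) || !nrow(diff)) return(diff[0, ])
    key <- function(d) paste(d$sender, d$receiver, d$ligand, d$receptor,
                             sep = "\r")
    sigLRI <- unique(key(lri)[lri$pAdj <= maxPAdj])
    magOK <- if (directional) diff$score >= minAbsDiff
             else abs(diff$score) >= minAbsDiff
    keep <- key(diff) %in% sigLRI & diff$pAdj <= maxPAdj &
        !is.na(diff$score) & magOK
    diff[keep, ]
}

#' Count significant interactions per sender/receiver pair
#'
#' @param sig filtered records from \code{\link{significantInteractions}}.
#' @param senders,receivers cell types spanning the table (defaults: those
#'   present in \code{sig}).
#' @return senders x receivers integer matrix whose grand total equals
#'   \code{nrow(sig)}.
#' @export
countSignificantByPair <- function(sig, senders = NULL, receivers = NULL) {
    if (is.null(senders)) senders <- sort(unique(sig$sender))
    if (is.null(receivers)) receivers <- sort(unique(sig$receiver))
    out <- matrix(0L, length(senders), length(receivers),
                  dimnames = list(senders, receivers))
    if (nrow(sig)) {
        tab <- table(factor(sig$sender, senders),
                     factor(sig$receiver, receivers))
        out[] <- as.integer(tab)
    }
    out
}

#' Min-max scale values to [0, 1]
#'
#' Used to display relative changes of ligand and receptor expression
#' between the two conditions: \code{(x - min) / (max - min)} across the
#' supplied values. Constant vectors map to all zeros by convention (with a
#' message).
#'
#' @param x numeric vector (e.g. a ligand's mean expression in the two
#'   conditions).
#' @return Values scaled into [0, 1].
#' @export
minmaxScalePairs <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) {
        message("constant values; min-max scaling maps them to 0")
        return(rep(0, length(x)))
    }
    (x - rng[1]) / (rng[2] - rng[1])
}
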