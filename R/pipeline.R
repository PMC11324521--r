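#' Run the full communication-analysis pipeline on a fixture directory
#'
#' Orchestrates the stages qc -> normalize -> (dge | lri | lri-diff |
#' modules) over a standard fixture directory (MTX + barcodes/features +
#' cells.csv + lr_pairs.csv), writing CSV outputs and a JSON run manifest.
#' A single global seed deterministically derives per-stage seeds, so
#' toggling stages does not shift downstream randomness; identical inputs,
#' parameters and seed produce byte-identical outputs.
#'
#' Outputs (per enabled stage): \code{qc_metrics.csv}, \code{kept_cells.txt},
#' \code{kept_genes.txt}; \code{dge_<type>.csv} and \code{radial.csv};
#' \code{lri_scores.csv}; \code{lri_diff.csv}, \code{lri_significant.csv}
#' and \code{lri_counts.csv}; \code{bins.csv}, \code{modules.csv} and
#' \code{module_profiles.csv}; plus \code{manifest.json}.
#'
#' @param countsDir directory with matrix.mtx, barcodes.tsv, features.tsv
#'   (cells.csv / lr_pairs.csv are read from here unless overridden).
#' @param outDir output directory (created).
#' @param cellsFile,lrFile optional overrides for the annotation and
#'   ligand-receptor tables.
#' @param stages subset of \code{c("qc", "dge", "lri", "lridiff",
#'   "modules")}.
#' @param seed global seed.
#' @param params named list overriding the stage defaults:
#'   \code{nPerm} (10000), \code{nBins} (21), \code{rMin} (0.5),
#'   \code{resolution} (1), \code{nHVG} (4000), \code{nHVGModules} (8000),
#'   \code{minFracLR} (0.1), \code{minFracDGE} (0.2), \code{maxPAdj}
#'   (0.05), \code{minAbsDiff} (1), \code{mitoPrefix} ("mt-"),
#'   \code{hemoPrefix} ("Hb"), \code{qc} (a \code{\link{qcThresholds}}).
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(countsDir, outDir,
                        cellsFile = NULL, lrFile = NULL,
                        stages = c("qc", "dge", "lri", "lridiff", "modules"),
                        seed = 1, params = list()) {
    p <- utils::modifyList(list(
        nPerm = 10000, nBins = 21, rMin = 0.5, resolution = 1,
        nHVG = 4000, nHVGModules = 8000, minFracLR = 0.1, minFracDGE = 0.2,
        maxPAdj = 0.05, minAbsDiff = 1, mitoPrefix = "mt-",
        hemoPrefix = "Hb", qc = qcThresholds()), params)
    stages <- match.arg(stages,
                        c("qc", "dge", "lri", "lridiff", "modules"),
                        several.ok = TRUE)
    if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
        stop("cannot create output directory: ", outDir)
    if (is.null(cellsFile)) cellsFile <- file.path(countsDir, "cells.csv")
    if (is.null(lrFile)) lrFile <- file.path(countsDir, "lr_pairs.csv")

    wcsv <- function(x, f) utils::write.csv(as.data.frame(x),
                                            file.path(outDir, f),
                                            row.names = FALSE)
    manifest <- list(package = "commshift",
                     version = as.character(utils::packageVersion("commshift")),
                     seed = seed,
                     stages = stages,
                     parameters = lapply(
                         p, function(v) if (is(v, "QCThresholds"))
                             list(minUMIs = v@minUMIs,
                                  minFeatures = v@minFeatures,
                                  maxPctMito = v@maxPctMito,
                                  maxPctHemo = v@maxPctHemo,
                                  minComplexity = v@minComplexity,
                                  geneMinCounts = v@geneMinCounts,
                                  geneMinBarcodes = v@geneMinBarcodes)
                         else v),
                     inputs = list(), records = list())
    for (f in c(file.path(countsDir, "matrix.mtx"), cellsFile, lrFile))
        if (file.exists(f))
            manifest$inputs[[basename(f)]] <- unname(tools::md5sum(f))

    counts <- readCounts(countsDir)
    cells <- utils::read.csv(cellsFile, stringsAsFactors = FALSE)
    rownames(cells) <- cells$cell_id
    cells <- cells[colnames(counts), , drop = FALSE]

    ## ---- qc (always computed; outputs written when enabled) ----
    mito <- genesByPrefix(counts, p$mitoPrefix)
    hemo <- genesByPrefix(counts, p$hemoPrefix)
    metrics <- barcodeMetrics(counts, mito, hemo)
    keptCells <- filterBarcodes(metrics, p$qc)
    keptGenes <- filterGenes(counts, p$qc)
    if ("qc" %in% stages) {
        m <- as.data.frame(metrics)
        m <- cbind(cell_id = rownames(m), m)
        wcsv(m, "qc_metrics.csv")
        writeLines(keptCells, file.path(outDir, "kept_cells.txt"))
        writeLines(keptGenes, file.path(outDir, "kept_genes.txt"))
    }
    manifest$records$qc <- list(keptCells = length(keptCells),
                                keptGenes = length(keptGenes))
    if (!length(keptCells) || !length(keptGenes))
        stop("stage qc: no ", if (length(keptCells)) "genes" else "barcodes",
             " pass the filters; adjust 'params$qc' for this dataset")
    counts <- counts[keptGenes, keptCells]
    cells <- cells[keptCells, , drop = FALSE]
    norm <- normalizeCounts(counts)

    ## ---- dge: per-cell-type condition comparison + radial data ----
    if ("dge" %in% stages) {
        conds <- sort(unique(cells$condition))
        if (length(conds) == 2) {
            mut <- conds[conds != "control"][1]
            ref <- setdiff(conds, mut)[1]
            resList <- list()
            for (ct in sort(unique(cells$cell_type))) {
                sel <- cells$cell_type == ct
                sub <- counts[, sel, drop = FALSE]
                frac <- fracExpressed(sub, cells[sel, , drop = FALSE],
                                      "condition")
                keep <- expressedGenes(frac, p$minFracDGE)
                if (length(keep) < 2) next
                pbct <- makePseudobulk(sub[keep, , drop = FALSE],
                                       cells[sel, , drop = FALSE],
                                       groupKey = "condition",
                                       sampleKey = "sample")
                res <- suppressWarnings(nbWaldTest(pbct, mut, ref))
                resList[[ct]] <- res
                wcsv(res, sprintf("dge_%s.csv", ct))
            }
            if (length(resList))
                wcsv(radialPlotData(resList, conditions = c(mut, ref)),
                     "radial.csv")
            manifest$records$dge <- list(cellTypes = length(resList))
        } else {
            message("dge stage skipped: need exactly 2 conditions")
            manifest$records$dge <- list(skipped = TRUE)
        }
    }

    ## ---- lri / lridiff ----
    needLR <- any(c("lri", "lridiff") %in% stages)
    if (needLR && file.exists(lrFile)) {
        db <- loadLRPairs(lrFile, norm, minFrac = p$minFracLR)
        if ("lri" %in% stages) {
            lri <- lriPermTest(norm, cells, db, nPerm = p$nPerm,
                               seed = .deriveSeed(seed, 1))
            wcsv(lri, "lri_scores.csv")
            manifest$records$lri <- list(records = nrow(lri),
                                         nPerm = p$nPerm)
        }
        if ("lridiff" %in% stages) {
            conds <- unique(cells$condition)
            ref <- if ("control" %in% conds) "control" else sort(conds)[1]
            diff <- lriDiffPermTest(norm, cells, db, nPerm = p$nPerm,
                                    seed = .deriveSeed(seed, 2),
                                    conditions = c(ref,
                                                   setdiff(conds, ref)[1]))
            wcsv(diff, "lri_diff.csv")
            manifest$records$lridiff <- list(records = nrow(diff),
                                             nPerm = p$nPerm)
            if ("lri" %in% stages) {
                sig <- significantInteractions(lri, diff,
                                               maxPAdj = p$maxPAdj,
                                               minAbsDiff = p$minAbsDiff)
                wcsv(sig, "lri_significant.csv")
                counts_tab <- countSignificantByPair(
                    sig, senders = sort(unique(cells$cell_type)),
                    receivers = sort(unique(cells$cell_type)))
                utils::write.csv(counts_tab,
                                 file.path(outDir, "lri_counts.csv"))
                manifest$records$significant <- nrow(sig)
            }
        }
    } else if (needLR) {
        message("lri stage(s) skipped: no lr_pairs table found")
    }

    ## ---- modules ----
    if ("modules" %in% stages) {
        pt <- cells$pseudotime
        names(pt) <- cells$cell_id
        pt <- pt[!is.na(pt)]
        if (length(pt) >= p$nBins) {
            bins <- binPseudotime(pt, nBins = p$nBins)
            nHVG <- min(p$nHVGModules, nrow(normValues(norm)))
            hvg <- selectHVG(norm, nHVG)
            prof <- suppressMessages(binProfiles(norm, bins, hvg))
            graph <- correlationGraph(prof, rMin = p$rMin)
            mods <- leidenModules(graph, resolution = p$resolution,
                                  seed = .deriveSeed(seed, 3))
            wcsv(data.frame(cell_id = names(bins), bin = unname(bins)),
                 "bins.csv")
            wcsv(mods, "modules.csv")
            wcsv(moduleSummaries(mods, prof), "module_profiles.csv")
            manifest$records$modules <-
                list(lineageCells = length(pt),
                     modules = length(setdiff(unique(mods$module),
                                              "unclustered")))
        } else {
            message("modules stage skipped: no usable pseudotime")
            manifest$records$modules <- list(skipped = TRUE)
        }
    }

    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
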