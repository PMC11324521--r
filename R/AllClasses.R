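#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom Matrix rowSums colSums rowMeans colMeans t Diagonal sparseMatrix readMM
NULL

#' Simulation configuration for synthetic scRNA-seq data
#'
#' Holds all parameters of the negative-binomial single-cell simulator:
#' cell-type structure, two experimental conditions, planted ligand-receptor
#' fold changes in designated sender/receiver types, and an optional
#' pseudotime lineage carrying temporal gene programs.
#'
#' @slot nCellTypes number of cell types.
#' @slot cellsPerType cells per type per condition (recycled to length
#'   \code{nCellTypes}).
#' @slot nGenes number of genes.
#' @slot baselineMean expected counts per gene per cell before type effects.
#' @slot dispersion negative-binomial size parameter theta
#'   (variance = mu + mu^2/theta).
#' @slot libsizeSigma log-normal sd of the per-cell size factor.
#' @slot typeSigma log-normal sd of per-type gene-mean multipliers (cell-type
#'   separability).
#' @slot geneSigma log-normal sd of baseline gene means.
#' @slot samplesPerCondition replicate samples per condition.
#' @slot conditions the two condition labels, reference first.
#' @slot plantedInteractions data.frame with columns \code{ligand},
#'   \code{receptor}, \code{sender}, \code{receiver}, \code{ligandFold},
#'   \code{receptorFold}; folds multiply the second-condition mean.
#' @slot plantedMean baseline mean of planted ligand/receptor genes in their
#'   sender/receiver type.
#' @slot plantedDispersion NB size parameter used for planted LR genes.
#' @slot nBackgroundPairs number of null ligand-receptor pairs to emit.
#' @slot trajectory list with elements \code{cellTypes} (lineage types),
#'   \code{modules} (list of \code{list(genes=, shape=)} with shape one of
#'   \code{"sigmoid_up"}, \code{"sigmoid_down"}, \code{"bump"},
#'   \code{"flat"}), and optional \code{amplitude}.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig", representation(
    nCellTypes = "integer",
    cellsPerType = "integer",
    nGenes = "integer",
    baselineMean = "numeric",
    dispersion = "numeric",
    libsizeSigma = "numeric",
    typeSigma = "numeric",
    geneSigma = "numeric",
    samplesPerCondition = "integer",
    conditions = "character",
    plantedInteractions = "data.frame",
    plantedMean = "numeric",
    plantedDispersion = "numeric",
    nBackgroundPairs = "integer",
    trajectory = "list",
    seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    chkPos <- function(x, nm) {
        if (length(x) < 1L || any(!is.finite(x)) || any(x <= 0))
            msg <<- c(msg, sprintf("'%s' must be positive", nm))
    }
    chkPos(object@nCellTypes, "nCellTypes")
    chkPos(object@cellsPerType, "cellsPerType")
    chkPos(object@nGenes, "nGenes")
    chkPos(object@baselineMean, "baselineMean")
    chkPos(object@dispersion, "dispersion")
    chkPos(object@plantedMean, "plantedMean")
    chkPos(object@plantedDispersion, "plantedDispersion")
    if (object@libsizeSigma < 0)
        msg <- c(msg, "'libsizeSigma' must be nonnegative")
    if (length(object@conditions) != 2L ||
        anyDuplicated(object@conditions))
        msg <- c(msg, "'conditions' must be two distinct labels")
    pi <- object@plantedInteractions
    if (nrow(pi)) {
        need <- c("ligand", "receptor", "sender", "receiver",
                  "ligandFold", "receptorFold")
        if (!all(need %in% names(pi))) {
            msg <- c(msg, paste("'plantedInteractions' needs columns",
                                paste(need, collapse = ", ")))
        } else {
            if (any(pi$ligandFold <= 0) || any(pi$receptorFold <= 0))
                msg <- c(msg, "planted fold factors must be > 0")
            pg <- c(pi$ligand, pi$receptor)
            if (anyDuplicated(pg))
                msg <- c(msg, "planted ligand/receptor genes must be distinct")
        }
    }
    traj <- object@trajectory
    if (length(traj)) {
        mods <- traj$modules
        allg <- unlist(lapply(mods, `[[`, "genes"))
        if (anyDuplicated(allg))
            msg <- c(msg, "trajectory module gene sets must be disjoint")
        shapes <- vapply(mods, `[[`, character(1), "shape")
        ok <- c("sigmoid_up", "sigmoid_down", "bump", "flat")
        if (!all(shapes %in% ok))
            msg <- c(msg, sprintf("module shapes must be in {%s}",
                                  paste(ok, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig Constructor with study defaults.
#'
#' @param nCellTypes,cellsPerType,nGenes,baselineMean,dispersion,libsizeSigma
#'   see slots.
#' @param typeSigma,geneSigma,samplesPerCondition,conditions see slots.
#' @param plantedInteractions,plantedMean,plantedDispersion see slots.
#' @param nBackgroundPairs,trajectory,seed see slots.
#' @return A validated \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nCellTypes = 2, cellsPerType = 20, nGenes = 50)
#' cfg
#' @export
simulationConfig <- function(nCellTypes = 4L,
                             cellsPerType = 250L,
                             nGenes = 300L,
                             baselineMean = 2,
                             dispersion = 2,
                             libsizeSigma = 0.3,
                             typeSigma = 1,
                             geneSigma = 0.5,
                             samplesPerCondition = 2L,
                             conditions = c("control", "cKO"),
                             plantedInteractions = NULL,
                             plantedMean = 30,
                             plantedDispersion = 10,
                             nBackgroundPairs = 50L,
                             trajectory = list(),
                             seed = 1L) {
    if (is.null(plantedInteractions))
        plantedInteractions <- data.frame(
            ligand = character(), receptor = character(),
            sender = character(), receiver = character(),
            ligandFold = numeric(), receptorFold = numeric(),
            stringsAsFactors = FALSE)
    new("SimulationConfig",
        nCellTypes = as.integer(nCellTypes),
        cellsPerType = rep_len(as.integer(cellsPerType), nCellTypes),
        nGenes = as.integer(nGenes),
        baselineMean = as.numeric(baselineMean),
        dispersion = as.numeric(dispersion),
        libsizeSigma = as.numeric(libsizeSigma),
        typeSigma = as.numeric(typeSigma),
        geneSigma = as.numeric(geneSigma),
        samplesPerCondition = as.integer(samplesPerCondition),
        conditions = as.character(conditions),
        plantedInteractions = plantedInteractions,
        plantedMean = as.numeric(plantedMean),
        plantedDispersion = as.numeric(plantedDispersion),
        nBackgroundPairs = as.integer(nBackgroundPairs),
        trajectory = trajectory,
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  %d cell types x %s cells/type/condition, %d genes\n",
                object@nCellTypes,
                paste(unique(object@cellsPerType), collapse = "/"),
                object@nGenes))
    cat(sprintf("  NB: baseline mean %.3g, size %.3g; libsize sigma %.3g\n",
                object@baselineMean, object@dispersion, object@libsizeSigma))
    cat(sprintf("  conditions: %s; %d planted interaction(s); %d background pair(s)\n",
                paste(object@conditions, collapse = " vs "),
                nrow(object@plantedInteractions), object@nBackgroundPairs))
    if (length(object@trajectory))
        cat(sprintf("  trajectory: %d module(s) over types %s\n",
                    length(object@trajectory$modules),
                    paste(object@trajectory$cellTypes, collapse = ",")))
    cat(sprintf("  seed: %d\n", object@seed))
})

#' Barcode and gene quality-control thresholds
#'
#' Default thresholds for barcode filtering (minimum UMIs and detected
#' features, maximum mitochondrial and hemoglobin count percentages, minimum
#' library complexity) and for gene filtering (minimum total counts across
#' at least a minimum number of distinct barcodes).
#'
#' A barcode is kept iff total counts >= \code{minUMIs}, detected features >=
#' \code{minFeatures}, mitochondrial percentage < \code{maxPctMito},
#' hemoglobin percentage < \code{maxPctHemo} and complexity >
#' \code{minComplexity} (strict inequalities where stated). A gene is kept
#' iff it has >= \code{geneMinCounts} total counts in >=
#' \code{geneMinBarcodes} distinct barcodes.
#'
#' @slot minUMIs,minFeatures,maxPctMito,maxPctHemo,minComplexity barcode
#'   thresholds.
#' @slot geneMinCounts,geneMinBarcodes gene thresholds.
#' @export
setClass("QCThresholds", representation(
    minUMIs = "numeric", minFeatures = "numeric",
    maxPctMito = "numeric", maxPctHemo = "numeric",
    minComplexity = "numeric",
    geneMinCounts = "numeric", geneMinBarcodes = "numeric"))

setValidity("QCThresholds", function(object) {
    vals <- c(object@minUMIs, object@minFeatures, object@maxPctMito,
              object@maxPctHemo, object@minComplexity,
              object@geneMinCounts, object@geneMinBarcodes)
    if (any(vals < 0)) "all thresholds must be >= 0" else TRUE
})

#' @describeIn QCThresholds Constructor with the default thresholds.
#' @param minUMIs,minFeatures,maxPctMito,maxPctHemo,minComplexity,geneMinCounts,geneMinBarcodes
#'   see slots.
#' @return A \code{QCThresholds} object.
#' @examples
#' qcThresholds()
#' @export
qcThresholds <- function(minUMIs = 1000, minFeatures = 800,
                         maxPctMito = 15, maxPctHemo = 5,
                         minComplexity = 0.8,
                         geneMinCounts = 10, geneMinBarcodes = 10) {
    new("QCThresholds", minUMIs = minUMIs, minFeatures = minFeatures,
        maxPctMito = maxPctMito, maxPctHemo = maxPctHemo,
        minComplexity = minComplexity, geneMinCounts = geneMinCounts,
        geneMinBarcodes = geneMinBarcodes)
}

setMethod("show", "QCThresholds", function(object) {
    cat("QCThresholds\n")
    cat(sprintf("  barcodes: UMIs >= %g, features >= %g, mito%% < %g, hemo%% < %g, complexity > %g\n",
                object@minUMIs, object@minFeatures, object@maxPctMito,
                object@maxPctHemo, object@minComplexity))
    cat(sprintf("  genes: >= %g counts in >= %g barcodes\n",
                object@geneMinCounts, object@geneMinBarcodes))
})

#' Depth-normalized expression matrix
#'
#' Container for a normalized genes x cells matrix together with the per-cell
#' size factors used, and a flag recording whether values were log1p
#' transformed.
#'
#' @slot values genes x cells matrix of normalized values.
#' @slot sizeFactors per-cell positive size factors.
#' @slot logTransformed whether \code{log1p} was applied.
#' @export
setClass("NormalizedMatrix", representation(
    values = "ANY", sizeFactors = "numeric", logTransformed = "logical"))

setValidity("NormalizedMatrix", function(object) {
    if (any(object@sizeFactors <= 0))
        return("size factors must be > 0")
    if (ncol(object@values) != length(object@sizeFactors))
        return("one size factor per cell required")
    TRUE
})

#' @describeIn NormalizedMatrix The normalized value matrix.
#' @param x a \code{NormalizedMatrix}.
#' @export
normValues <- function(x) {
    if (is(x, "NormalizedMatrix")) x@values else x
}

#' @describeIn NormalizedMatrix Per-cell size factors.
#' @export
normSizeFactors <- function(x) x@sizeFactors

setMethod("show", "NormalizedMatrix", function(object) {
    cat(sprintf("NormalizedMatrix: %d genes x %d cells (%s)\n",
                nrow(object@values), ncol(object@values),
                if (object@logTransformed) "log1p" else "linear"))
    cat(sprintf("  size factors: median %.3g, range [%.3g, %.3g]\n",
                stats::median(object@sizeFactors),
                min(object@sizeFactors), max(object@sizeFactors)))
})
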