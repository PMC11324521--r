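# Independent oracles and small fixture builders used across tests.

# All permutations of 1..n as rows (n small).
permutationsOf <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- permutationsOf(n - 1L)
    out <- matrix(0L, 0, n)
    for (k in seq_len(n)) {
        rest <- setdiff(seq_len(n), k)
        out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
    }
    out
}

# Benjamini-Hochberg step-up, written independently of stats::p.adjust.
bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    ranked <- p[o] * n / seq_len(n)
    adj <- pmin(rev(cummin(rev(ranked))), 1)
    out <- numeric(n)
    out[o] <- adj
    out
}

# Exact permutation p-values for the product interaction score by exhaustive
# enumeration of every cell-type label reassignment (single condition).
# Returns a data.frame keyed by (sender, receiver, ligand, receptor).
lriExactOracle <- function(vals, typeLabels, db) {
    vals <- as.matrix(vals)
    n <- ncol(vals)
    types <- sort(unique(typeLabels))
    meansOf <- function(lab) {
        sapply(types, function(t)
            rowMeans(vals[, lab == t, drop = FALSE]))
    }
    scoreTable <- function(lab) {
        M <- meansOf(lab)
        out <- expand.grid(pair = seq_len(nrow(db)), sender = types,
                           receiver = types, stringsAsFactors = FALSE)
        out$score <- M[cbind(db$ligand[out$pair], out$sender)] *
            M[cbind(db$receptor[out$pair], out$receiver)]
        out
    }
    obs <- scoreTable(typeLabels)
    perms <- permutationsOf(n)
    hits <- numeric(nrow(obs))
    for (i in seq_len(nrow(perms))) {
        s <- scoreTable(typeLabels[perms[i, ]])$score
        hits <- hits + (s >= obs$score)
    }
    data.frame(sender = obs$sender, receiver = obs$receiver,
               ligand = db$ligand[obs$pair], receptor = db$receptor[obs$pair],
               pExact = hits / nrow(perms))
}

# Dense named count matrix helper.
namedMatrix <- function(x, nGenes, nCells, genePrefix = "g",
                        cellPrefix = "c") {
    matrix(x, nGenes, nCells,
           dimnames = list(sprintf("%s%03d", genePrefix, seq_len(nGenes)),
                           sprintf("%s%03d", cellPrefix, seq_len(nCells))))
}

# The planted-interaction layout used by the recovery studies: 20 directed
# interactions among 5 types (all ordered non-self type pairs), planted
# diffs cycling over the given values with equal ligand and receptor folds.
recoveryDesign <- function(diffs = c(1.2, 1.5, 2.0)) {
    types <- paste0("type", 1:5)
    combos <- expand.grid(sender = types, receiver = types,
                          stringsAsFactors = FALSE)
    combos <- combos[combos$sender != combos$receiver, ][1:20, ]
    d <- rep(diffs, length.out = 20)
    list(
        interactions = data.frame(
            ligand = sprintf("gene%04d", 1:20),
            receptor = sprintf("gene%04d", 21:40),
            sender = combos$sender, receiver = combos$receiver,
            ligandFold = 2^d, receptorFold = 2^d,
            stringsAsFactors = FALSE),
        trueDiff = d)
}

recoveryConfig <- function(seed, design = recoveryDesign()) {
    simulationConfig(nCellTypes = 5, cellsPerType = 200, nGenes = 600,
                     baselineMean = 30, dispersion = 2, plantedMean = 25,
                     plantedDispersion = 100,
                     plantedInteractions = design$interactions,
                     nBackgroundPairs = 50, seed = seed)
}

# Normalized matrix + annotation from a simulated dataset.
normAnn <- function(sce) {
    counts <- SummarizedExperiment::assay(sce, "counts")
    list(norm = normalizeCounts(counts),
         ann = as.data.frame(SummarizedExperiment::colData(sce)),
         counts = counts)
}
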