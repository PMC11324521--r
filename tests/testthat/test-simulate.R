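test_that("planted ground truth follows the fold configuration", {
    pi1 <- data.frame(ligand = "gene0001", receptor = "gene0002",
                      sender = "type1", receiver = "type2",
                      ligandFold = 1, receptorFold = 1)
    cfg <- simulationConfig(nCellTypes = 2, cellsPerType = 15, nGenes = 30,
                            plantedInteractions = pi1, nBackgroundPairs = 2,
                            seed = 1)
    truth <- S4Vectors::metadata(simulateDataset(cfg))$truth
    expect_equal(truth$lriDiff$trueDiff, 0)

    pi2 <- transform(pi1, ligandFold = 4, receptorFold = 1)
    cfg2 <- simulationConfig(nCellTypes = 2, cellsPerType = 15, nGenes = 30,
                             plantedInteractions = pi2, nBackgroundPairs = 2,
                             seed = 1)
    truth2 <- S4Vectors::metadata(simulateDataset(cfg2))$truth
    expect_equal(truth2$lriDiff$trueDiff, 1)  # (log2 4 + log2 1)/2
})

test_that("counts reproduce the negative-binomial moments", {
    ## 10,000 draws per gene at mu = 5, theta = 2: mean ~5, var ~17.5
    cfg <- simulationConfig(nCellTypes = 1, cellsPerType = 5000, nGenes = 4,
                            baselineMean = 5, dispersion = 2,
                            libsizeSigma = 0, typeSigma = 0, geneSigma = 0,
                            nBackgroundPairs = 0, seed = 42)
    counts <- as.matrix(SummarizedExperiment::assay(simulateDataset(cfg)))
    mu <- rowMeans(counts)
    v <- apply(counts, 1, var)
    expect_true(all(abs(mu - 5) / 5 < 0.05))
    expect_true(all(abs(v - 17.5) / 17.5 < 0.05))
})

test_that("simulation is deterministic for a fixed seed", {
    cfg <- simulationConfig(nCellTypes = 2, cellsPerType = 25, nGenes = 40,
                            nBackgroundPairs = 5, seed = 9)
    a <- simulateDataset(cfg)
    b <- simulateDataset(cfg)
    expect_identical(as.matrix(SummarizedExperiment::assay(a)),
                     as.matrix(SummarizedExperiment::assay(b)))
    expect_identical(S4Vectors::metadata(a)$lrPairs,
                     S4Vectors::metadata(b)$lrPairs)
})

test_that("planted fold changes are identifiable from group means", {
    pi <- data.frame(ligand = "gene0001", receptor = "gene0002",
                     sender = "type1", receiver = "type2",
                     ligandFold = 4, receptorFold = 2)
    cfg <- simulationConfig(nCellTypes = 2, cellsPerType = 2000, nGenes = 30,
                            libsizeSigma = 0, plantedMean = 20,
                            plantedDispersion = 10,
                            plantedInteractions = pi, nBackgroundPairs = 0,
                            seed = 5)
    sce <- simulateDataset(cfg)
    counts <- as.matrix(SummarizedExperiment::assay(sce))
    cd <- SummarizedExperiment::colData(sce)
    grpMean <- function(gene, type, cond)
        mean(counts[gene, cd$cell_type == type & cd$condition == cond])
    expect_equal(grpMean("gene0001", "type1", "cKO") /
                 grpMean("gene0001", "type1", "control"), 4,
                 tolerance = 0.05)
    expect_equal(grpMean("gene0002", "type2", "cKO") /
                 grpMean("gene0002", "type2", "control"), 2,
                 tolerance = 0.05)
})

test_that("invalid configurations are rejected with the offending field", {
    expect_error(simulationConfig(nGenes = -1), "nGenes")
    expect_error(simulationConfig(dispersion = 0), "dispersion")
    expect_error(simulationConfig(
        plantedInteractions = data.frame(
            ligand = "gene0001", receptor = "gene0002", sender = "type1",
            receiver = "type2", ligandFold = 0, receptorFold = 1)),
        "fold")
    expect_error(simulationConfig(
        plantedInteractions = data.frame(
            ligand = "gene0001", receptor = "gene0001", sender = "type1",
            receiver = "type2", ligandFold = 2, receptorFold = 2)),
        "distinct")
})

test_that("trajectory cells carry pseudotime and module genes follow it", {
    traj <- list(cellTypes = "type1",
                 modules = list(up = list(genes = sprintf("gene%04d", 1:5),
                                          shape = "sigmoid_up")))
    cfg <- simulationConfig(nCellTypes = 2, cellsPerType = 300, nGenes = 50,
                            libsizeSigma = 0, trajectory = traj,
                            nBackgroundPairs = 0, seed = 2)
    sce <- simulateDataset(cfg)
    cd <- SummarizedExperiment::colData(sce)
    lineage <- cd$cell_type == "type1"
    expect_true(all(is.finite(cd$pseudotime[lineage])))
    expect_true(all(cd$pseudotime[lineage] >= 0 &
                    cd$pseudotime[lineage] <= 1))
    expect_true(all(is.na(cd$pseudotime[!lineage])))
    truth <- S4Vectors::metadata(sce)$truth
    expect_setequal(names(truth$moduleMembership), sprintf("gene%04d", 1:5))
    ## sigmoid-up genes: late cells express more than early cells
    counts <- as.matrix(SummarizedExperiment::assay(sce))
    pt <- cd$pseudotime[lineage]
    late <- counts[1:5, lineage][, pt > 0.7]
    early <- counts[1:5, lineage][, pt < 0.3]
    expect_true(all(rowMeans(late) > rowMeans(early)))
})
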