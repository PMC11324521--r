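test_that("pseudobulk sums counts per (group, sample) and conserves totals", {
    m <- namedMatrix(c(3, 1, 4, 2, 5, 0, 1, 1), 2, 4)
    ann <- data.frame(cell_type = c("A", "A", "B", "B"),
                      sample = c("s1", "s1", "s1", "s2"))
    pb <- makePseudobulk(m, ann)
    k <- SummarizedExperiment::assay(pb)
    expect_equal(sum(k), sum(m))
    expect_equal(unname(k[, "A|s1"]), c(3 + 4, 1 + 2))  # 2 cells summed
    expect_equal(unname(k[, "B|s2"]), m[, 4],
                 ignore_attr = TRUE)                     # single cell
    expect_equal(as.character(SummarizedExperiment::colData(pb)$group),
                 c("A", "B", "B"))
})

test_that("identical group profiles give zero log2FC and p near 1", {
    set.seed(2)
    base <- matrix(rpois(400, 50), 100, 4)
    k <- cbind(base, base)
    rownames(k) <- sprintf("g%03d", 1:100)
    colnames(k) <- sprintf("s%d", 1:8)
    res <- suppressWarnings(
        nbWaldTest(k, "A", "B", groups = rep(c("A", "B"), each = 4)))
    expect_equal(res$log2FC, rep(0, nrow(res)), tolerance = 1e-6)
    expect_true(all(res$p > 0.999))
})

test_that("median-of-ratios size factors absorb pure depth shifts", {
    set.seed(4)
    base <- matrix(rnbinom(600 * 4, mu = 200, size = 50), 600, 4)
    k <- cbind(base * 2L, base)   # group A counts exactly 2x group B
    rownames(k) <- sprintf("g%03d", 1:600)
    ## hand-computed factors: ratio to the geometric-mean reference gene
    ## profile doubles for the A columns
    logk <- log(k); ref <- rowMeans(logk)
    use <- is.finite(ref)
    sfHand <- apply(logk[use, ], 2, function(cc) exp(median(cc - ref[use])))
    res <- nbWaldTest(k, "A", "B", groups = rep(c("A", "B"), each = 4))
    expect_equal(unname(S4Vectors::metadata(res)$sizeFactors),
                 unname(sfHand))
    expect_equal(sfHand[1:4] / sfHand[5:8], rep(2, 4),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_lt(max(abs(res$log2FC)), 0.2)
    expect_lt(mean(res$p <= 0.05), 0.08)
})

test_that("a single doubled gene is recovered at log2FC ~ 1", {
    set.seed(5)
    mu <- rep(500, 400)
    kB <- matrix(rnbinom(400 * 4, mu = mu, size = 200), 400, 4)
    kA <- matrix(rnbinom(400 * 4, mu = mu, size = 200), 400, 4)
    kA[1, ] <- rnbinom(4, mu = 2 * mu[1], size = 200)
    k <- cbind(kA, kB)
    rownames(k) <- sprintf("g%03d", 1:400)
    res <- nbWaldTest(k, "A", "B", groups = rep(c("A", "B"), each = 4))
    expect_equal(res["g001", "log2FC"], 1, tolerance = 0.05)
    expect_lt(res["g001", "pAdj"], 0.05)
})

test_that("all-zero genes are excluded and reported", {
    k <- namedMatrix(5, 10, 6)
    k[3, ] <- 0
    res <- suppressWarnings(
        nbWaldTest(k, "A", "B", groups = rep(c("A", "B"), each = 3)))
    expect_false("g003" %in% res$gene)
    expect_identical(S4Vectors::metadata(res)$excluded, "g003")
})

test_that("expressed fractions follow the either-condition rule", {
    m <- namedMatrix(0, 3, 20)
    ann <- data.frame(condition = rep(c("ctl", "mut"), each = 10))
    m[1, 1:2] <- 1                    # 0.2 in ctl, 0 in mut -> kept
    m[2, c(1, 11)] <- 1               # 0.1 in both -> dropped
    m[3, 11:15] <- 1                  # 0 in ctl, 0.5 in mut -> kept
    frac <- fracExpressed(m, ann, "condition")
    expect_equal(frac["g001", "ctl"], 0.2)
    expect_equal(frac["g002", "mut"], 0.1)
    expect_setequal(expressedGenes(frac, 0.2), c("g001", "g003"))
})
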