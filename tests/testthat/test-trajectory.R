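test_that("equal-count binning follows the remainder rule", {
    pt <- setNames(seq_len(42) / 42, sprintf("c%03d", 1:42))
    b <- binPseudotime(sample(pt), nBins = 21)
    expect_true(all(table(b) == 2))

    pt43 <- setNames(runif(43), sprintf("c%03d", 1:43))
    b43 <- binPseudotime(pt43, nBins = 21)
    sizes <- as.integer(table(b43))
    expect_equal(sizes[1], 3)                 # the extra cell in bin 1
    expect_true(all(sizes[-1] == 2))
    expect_equal(b43[names(which.max(pt43))], c(21L),
                 ignore_attr = TRUE)          # max pseudotime -> last bin
    expect_error(binPseudotime(pt43[1:10], nBins = 21), "cannot fill")
    expect_error(binPseudotime(c(a = 1, b = NA), nBins = 1), "finite")
})

test_that("binning is invariant to monotone pseudotime transforms", {
    set.seed(8)
    pt <- setNames(runif(100), sprintf("c%03d", 1:100))
    expect_identical(binPseudotime(pt), binPseudotime(qlogis(pt) * 3 + 5))
})

test_that("bin profiles are z-scaled per gene and drop constants", {
    set.seed(9)
    n <- 84
    pt <- setNames(sort(runif(n)), sprintf("c%03d", 1:n))
    m <- namedMatrix(0, 3, n)
    m[1, ] <- seq_len(n)          # monotone increasing
    m[2, ] <- rpois(n, 20)
    m[3, ] <- 7                   # constant -> dropped
    bins <- binPseudotime(pt)
    expect_message(prof <- binProfiles(m, bins), "constant")
    expect_false("g003" %in% rownames(prof))
    expect_equal(unname(rowMeans(prof)), rep(0, 2))
    expect_equal(unname(apply(prof, 1, sd)), rep(1, 2))
    expect_true(all(diff(prof["g001", ]) > 0))  # monotone planted gene
})

test_that("correlation edges require r strictly above the threshold", {
    prof <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1),
                  d = c(2, 1, 3))
    g <- correlationGraph(prof, rMin = 0.5)
    ## a~b identical up to scale: edge with weight 1; a~c anticorrelated:
    ## none; a~d has r = 0.5 exactly: excluded by the strict rule
    expect_equal(igraph::ecount(g), 1)
    e <- igraph::as_data_frame(g)
    expect_setequal(unlist(e[c("from", "to")]), c("a", "b"))
    expect_equal(e$weight, 1)
    expect_equal(cor(prof["a", ], prof["d", ]), 0.5)   # boundary case
    expect_error(correlationGraph(prof[1, , drop = FALSE]), "2 genes")
})

test_that("Leiden modules recover disconnected cliques deterministically", {
    ## two blocks of perfectly correlated profiles + one isolated gene
    base1 <- sin(seq(0, 3, length.out = 21))
    base2 <- cos(seq(0, 3, length.out = 21))
    prof <- rbind(
        t(sapply(1:4, function(i) base1 * i)),
        t(sapply(1:3, function(i) base2 * i)),
        runif(21))
    rownames(prof) <- c(paste0("u", 1:4), paste0("v", 1:3), "iso")
    g <- correlationGraph(prof, rMin = 0.99)
    mods <- leidenModules(g, seed = 5)
    expect_equal(mods$module[mods$gene == "iso"], "unclustered")
    expect_equal(mods$module[mods$gene %in% paste0("u", 1:4)],
                 rep("M1", 4))   # larger clique labeled first
    expect_equal(mods$module[mods$gene %in% paste0("v", 1:3)],
                 rep("M2", 3))
    expect_identical(mods, leidenModules(g, seed = 5))
    gEmpty <- correlationGraph(rbind(a = base1, b = -base1), rMin = 0.5)
    expect_warning(m0 <- leidenModules(gEmpty), "empty")
    expect_true(all(m0$module == "unclustered"))
})

test_that("module summaries shrink their confidence band as 1/sqrt(m)", {
    set.seed(10)
    profile <- sin(seq(0, 2, length.out = 21))
    widths <- sapply(c(4, 16, 64), function(m) {
        P <- t(sapply(seq_len(m),
                      function(i) profile + rnorm(21, sd = 0.3)))
        rownames(P) <- paste0("g", seq_len(m))
        mods <- data.frame(gene = rownames(P), module = "M1")
        s <- moduleSummaries(mods, P)
        mean(s$ciHi - s$ciLo)
    })
    expect_equal(widths[1] / widths[2], 2, tolerance = 0.25)
    expect_equal(widths[2] / widths[3], 2, tolerance = 0.25)
    ## identical members and singleton modules give zero-width bands
    P2 <- rbind(g1 = profile, g2 = profile)
    s2 <- moduleSummaries(data.frame(gene = c("g1", "g2"), module = "M1"),
                          P2)
    expect_equal(s2$ciHi, s2$ciLo)
    s1 <- moduleSummaries(data.frame(gene = "g1", module = "M1"),
                          P2["g1", , drop = FALSE])
    expect_true(all(s1$degenerate))
    expect_equal(s1$ciHi, s1$ciLo)
})
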