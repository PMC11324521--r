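test_that("pair loading collapses reversed duplicates and filters by
           expressed fraction", {
    m <- namedMatrix(0, 4, 100)
    m[1, ] <- 1                 # g001: 100% of cells
    m[2, 1:50] <- 1             # g002: 50%
    m[3, 1:9] <- 1              # g003: 9% -> excluded
    m[4, 1:10] <- 1             # g004: 10% -> kept (strict "less than 10%")
    pairs <- data.frame(
        ligand = c("g001", "g002", "g001", "g001", "missing"),
        receptor = c("g002", "g001", "g003", "g004", "g001"))
    expect_warning(db <- loadLRPairs(pairs, m), "absent")
    ## (g002, g001) is the reversed duplicate of (g001, g002); (g001, g003)
    ## fails the fraction filter; the unknown gene is dropped
    expect_equal(db, data.frame(ligand = c("g001", "g001"),
                                receptor = c("g002", "g004")))
    expect_error(suppressWarnings(
        loadLRPairs(data.frame(ligand = "g003", receptor = "g003b"), m)),
        "survive|absent")
})

test_that("group means are plain arithmetic means per type and condition", {
    m <- namedMatrix(0, 2, 4)
    m[1, ] <- c(2, 4, 7, 0)
    ann <- data.frame(cell_type = c("A", "A", "B", "B"),
                      condition = c("x", "x", "x", "y"))
    gm <- groupMeans(m, ann)
    expect_equal(gm["g001", "A", "x"], 3)     # mean of 2 and 4
    expect_equal(gm["g001", "B", "x"], 7)     # single cell
    expect_equal(gm["g001", "B", "y"], 0)
    expect_true(is.na(gm["g001", "A", "y"]))  # empty group
    expect_equal(gm["g002", "A", "x"], 0)     # all-zero gene
})

test_that("interaction scores are directional products of Lmean and Rmean", {
    gm <- array(c(2, 3,   5, 7), dim = c(1, 2, 2),
                dimnames = list("g001", c("S", "R"), c("c1", "c2")))
    db <- data.frame(ligand = "g001", receptor = "g001")
    sc <- lriScores(gm, db)
    fetch <- function(s, r, k)
        sc$score[sc$sender == s & sc$receiver == r & sc$condition == k]
    expect_equal(fetch("S", "R", "c1"), 2 * 3)
    expect_equal(fetch("R", "S", "c1"), 3 * 2)
    expect_equal(fetch("S", "S", "c2"), 25)      # self-pairing included
    gm[1, 1, 1] <- 0
    expect_equal(lriScores(gm, db)$score[1], 0)  # zero Lmean -> zero score
})

test_that("diff scores follow the mean-of-log2-ratios equation", {
    mkMeans <- function(lc, rc, lk, rk)
        array(c(lc, 0, 0, rc,  lk, 0, 0, rk), dim = c(2, 2, 2),
              dimnames = list(c("L", "R"), c("S", "T"),
                              c("control", "cKO")))
    db <- data.frame(ligand = "L", receptor = "R")
    pick <- function(d) d$score[d$sender == "S" & d$receiver == "T"]
    ## both means double -> 1; identical -> 0; ligand x4 only -> 1
    expect_equal(pick(lriDiffScores(mkMeans(2, 3, 4, 6), db, epsilon = 0)), 1)
    expect_equal(pick(lriDiffScores(mkMeans(2, 3, 2, 3), db, epsilon = 0)), 0)
    expect_equal(pick(lriDiffScores(mkMeans(2, 3, 8, 3), db, epsilon = 0)), 1)
})

test_that("diff scores negate exactly under condition swap", {
    set.seed(21)
    for (i in 1:20) {
        means <- array(rgamma(8, 2, 1), dim = c(2, 2, 2),
                       dimnames = list(c("L", "R"), c("S", "T"),
                                       c("a", "b")))
        db <- data.frame(ligand = "L", receptor = "R")
        fwd <- lriDiffScores(means, db, conditions = c("a", "b"))
        rev <- lriDiffScores(means, db, conditions = c("b", "a"))
        expect_identical(fwd$score, -rev$score)
    }
})

test_that("zero means with epsilon disabled are flagged undefined", {
    means <- array(c(0, 1, 1, 1,  2, 1, 1, 1), dim = c(2, 2, 2),
                   dimnames = list(c("L", "R"), c("S", "T"), c("c", "k")))
    db <- data.frame(ligand = "L", receptor = "R")
    d0 <- lriDiffScores(means, db, epsilon = 0)
    bad <- d0$sender == "S"
    expect_true(all(d0$undefined[bad & d0$ligand == "L"][1]))
    expect_true(all(is.na(d0$score[d0$undefined])))
    d1 <- lriDiffScores(means, db, epsilon = 1e-9)
    expect_false(any(d1$undefined))
})

test_that("significance filtering applies the published conjunction", {
    lri <- S4Vectors::DataFrame(
        sender = c("S", "S", "S"), receiver = c("R", "R", "R"),
        ligand = c("l1", "l2", "l3"), receptor = c("r1", "r2", "r3"),
        condition = "cKO", lmean = 1, rmean = 1, score = 1,
        p = 0.01, pAdj = c(0.01, 0.01, 0.5), z = 1)
    diff <- S4Vectors::DataFrame(
        sender = "S", receiver = "R",
        ligand = c("l1", "l2", "l3"), receptor = c("r1", "r2", "r3"),
        lmeanControl = 1, rmeanControl = 1, lmeanMutant = 2, rmeanMutant = 2,
        score = c(1.5, 0.9, 1.5), undefined = FALSE,
        p = 0.001, pAdj = c(0.01, 0.01, 0.01))
    sig <- significantInteractions(lri, diff)
    ## l2 fails |diff| >= 1; l3 fails the LRI adjusted-p in any condition
    expect_identical(sig$ligand, "l1")
    expect_equal(nrow(significantInteractions(lri[0, ], diff[0, ])), 0)
    ## negative scores pass the absolute bound but not the directional one
    ## (l3 still fails the LRI leg, so 2 of 3 survive)
    diff$score <- c(-1.5, -1.5, -1.5)
    expect_equal(nrow(significantInteractions(lri, diff)), 2)
    expect_equal(nrow(significantInteractions(lri, diff,
                                              directional = TRUE)), 0)
})

test_that("per-pair counts conserve the filtered record total", {
    sig <- S4Vectors::DataFrame(sender = c("A", "A", "A", "B"),
                                receiver = c("B", "B", "C", "C"))
    tab <- countSignificantByPair(sig, c("A", "B", "C"), c("A", "B", "C"))
    expect_equal(sum(tab), 4)
    expect_equal(tab["A", "B"], 2L)
    expect_equal(tab["A", "C"], 1L)
    expect_equal(sum(countSignificantByPair(sig[0, ], "A", "B")), 0)
})

test_that("min-max scaling maps to [0,1] with a zero convention for
           constants", {
    expect_equal(minmaxScalePairs(c(2, 6)), c(0, 1))
    expect_message(z <- minmaxScalePairs(c(4, 4)), "constant")
    expect_equal(z, c(0, 0))
    set.seed(2)
    x <- minmaxScalePairs(rnorm(50))
    expect_true(all(x >= 0 & x <= 1))
})
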