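test_that("a single breakable entry gives E_raw = 1; invalid codes error", {
    mat <- matrix(c(1, 0), 1, 2, dimnames = list("solo", c("tgt", "n1")))
    land <- landscapeFromBinary(mat, "tgt")
    q <- eRaw(land, "solo", nSims = 50, seed = 1)
    expect_equal(q@eRaw, 1)
    expect_true(all(q@perSimFlips == 1))

    bad <- matrix(c(1, 1), 1, 2, dimnames = list("broad", c("tgt", "n1")))
    landBad <- landscapeFromBinary(bad, "tgt")
    expect_error(eRaw(landBad, "broad"), "not a valid VEnCode")
})

test_that("Monte-Carlo E_raw matches the exact expectation within 3 SE", {
    set.seed(401)
    cases <- list(c(c = 3, k = 2), c(c = 4, k = 3), c(c = 5, k = 2),
                  c(c = 7, k = 2), c(c = 13, k = 1), c(c = 4, k = 4))
    for (cs in cases) {
        c <- cs[["c"]]; k <- cs[["k"]]
        # random valid code: alibi column per RE, random extra inactives
        sub <- matrix(runif(k * (c - 1)) < 0.5, k, c - 1)
        for (j in seq_len(c - 1))
            if (all(sub[, j])) sub[sample.int(k, 1), j] <- FALSE
        mat <- cbind(1, sub + 0)
        colnames(mat) <- c("tgt", sprintf("n%02d", seq_len(c - 1)))
        rownames(mat) <- sprintf("re%02d", seq_len(k))
        land <- landscapeFromBinary(mat, "tgt")
        q <- eRaw(land, rownames(mat), nSims = 2000, seed = c * 10 + k)
        colSizes <- colSums(!sub)
        exact <- exactExpectedFlips(colSizes)
        expect_lt(abs(q@eRaw - exact), 3 * eStandardError(q) + 1e-12,
                  label = sprintf("c=%d k=%d |%.3f - %.3f|",
                                  c, k, q@eRaw, exact))
    }
})

test_that("E_best is exact at tiny sizes and monotone in c and k", {
    expect_equal(eBest(2, 1, nSims = 100, seed = 1), 1)
    # c=2, k=2: both entries must flip before the single column completes
    expect_equal(eBest(2, 2, nSims = 100, seed = 1), 2)

    # memoized per (c, k, nSims, seed)
    t1 <- eBest(5, 3, nSims = 2000, seed = 2)
    expect_identical(eBest(5, 3, nSims = 2000, seed = 2), t1)

    # monotone non-decreasing in both arguments, against the exact oracle
    grid <- matrix(NA_real_, 4, 4)
    for (c in 2:5) for (k in 1:4)
        grid[c - 1, k] <- exactExpectedFlips(rep(k, c - 1))
    expect_true(all(apply(grid, 1, diff) >= 0))
    expect_true(all(apply(grid, 2, diff) >= 0))

    # Monte-Carlo estimate tracks the oracle
    expect_lt(abs(eBest(5, 3, nSims = 2000, seed = 2) -
                  exactExpectedFlips(rep(3, 4))), 0.25)
})

test_that("normalization scales to E = 100 for best cases, warns above", {
    q <- new("QualityScore", eRaw = 2, nSims = 10L,
             perSimFlips = rep(2, 10))
    n1 <- normalizeE(q, c = 3, k = 2, nSims = 500, seed = 3)
    expect_equal(n1@e, 100 * 2 / n1@eBest)

    qBig <- new("QualityScore", eRaw = 100, nSims = 10L,
                perSimFlips = rep(100, 10))
    expect_warning(normalizeE(qBig, c = 3, k = 2, nSims = 500, seed = 3),
                   "exceeds 100")

    # a literal best-case code scores 100 within Monte-Carlo error
    c <- 6; k <- 3
    mat <- cbind(1, matrix(0, k, c - 1))
    colnames(mat) <- c("tgt", sprintf("n%02d", seq_len(c - 1)))
    rownames(mat) <- sprintf("re%02d", seq_len(k))
    land <- landscapeFromBinary(mat, "tgt")
    # E slightly above 100 is legitimate Monte-Carlo noise here
    q <- suppressWarnings(
        scoreVEnCode(land, rownames(mat), nSims = 2000, seed = 7))
    seE <- 100 * eStandardError(q) / q@eBest
    # both the score and the reference are Monte-Carlo draws, so the SE of
    # their ratio is ~sqrt(2) times the per-estimate SE
    expect_lt(abs(q@e - 100), 3 * sqrt(2) * seE)

    # larger codes withstand more false negatives (E_raw grows with k)
    e1 <- eBest(6, 1, nSims = 2000, seed = 8)
    e2 <- eBest(6, 2, nSims = 2000, seed = 8)
    e3 <- eBest(6, 3, nSims = 2000, seed = 8)
    expect_true(e1 < e2 && e2 < e3)
})

test_that("z equals exhaustive hold-out recomputation on toy tables", {
    # hand-built table: 1 target with 3 donors, 2 non-target cell types
    set.seed(405)
    prof <- generateLandscape(5, 10, donorsPerType = 3,
                              planted = list(target = "tgt", k = 2),
                              backgroundSparsity = 0.3, seed = 77)
    got <- donorHoldOutZ(prof, "tgt", trainSize = 1, method = "sampling",
                         k = 2, nSamples = 10000, quota = 100000, seed = 1)
    oracle <- zOracle(prof, "tgt", 1, 2)
    expect_equal(got@perSubsetZ, oracle)
    expect_equal(got@z, mean(oracle, na.rm = TRUE))

    # held-out donor identical to the training donor: z = 100
    x <- rbind(reA = c(2, 2, 0), reB = c(1, 1, 3))
    same <- makeProfiles(x, cellType = c("tgt", "tgt", "nt"),
                         donor = c("d1", "d2", "d1"))
    z1 <- donorHoldOutZ(same, "tgt", donorsTrain = "d1",
                        method = "sampling", k = 1, nSamples = 100,
                        seed = 1)
    expect_equal(z1@z, 100)

    # held-out donor with all-zero TPM: z = 0
    x2 <- rbind(reA = c(2, 0, 0), reB = c(1, 0, 3))
    zero <- makeProfiles(x2, cellType = c("tgt", "tgt", "nt"),
                         donor = c("d1", "d2", "d1"))
    z0 <- donorHoldOutZ(zero, "tgt", donorsTrain = "d1",
                        method = "sampling", k = 1, nSamples = 100,
                        seed = 1)
    expect_equal(z0@z, 0)

    single <- makeProfiles(rbind(reA = c(2, 0)),
                           cellType = c("tgt", "nt"),
                           donor = c("d1", "d1"))
    expect_error(donorHoldOutZ(single, "tgt", trainSize = 1),
                 "fewer than 2 donors")
})
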