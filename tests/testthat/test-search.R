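test_that("exclusivity test agrees with the truth-table oracle", {
    set.seed(301)
    for (i in 1:5) {
        mat <- randomBinaryDesign(12, 8)
        land <- landscapeFromBinary(mat, "tgt")
        ids <- reIds(land)
        for (res in utils::combn(ids, 3, simplify = FALSE))
            expect_identical(isVEnCode(land, res),
                             cnfExclusive(mat, "tgt", res))
    }
    land <- landscapeFromBinary(randomBinaryDesign(5, 4), "tgt")
    expect_error(isVEnCode(land, c("re01", "nope")), "unknown RE")

    # k = 1: an RE active only in the target is a code by definition
    mat <- matrix(c(1, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE,
                  dimnames = list(c("solo", "broad"),
                                  c("tgt", "n1", "n2")))
    land <- landscapeFromBinary(mat, "tgt")
    expect_true(isVEnCode(land, "solo"))
    expect_false(isVEnCode(land, "broad"))
    # a pair whose union of active columns covers every cell type fails
    expect_true(isVEnCode(land, c("solo", "broad")))  # solo still blocks
    mat["solo", "n1"] <- 1                 # now n1 is co-active for both
    land <- landscapeFromBinary(mat, "tgt")
    expect_false(isVEnCode(land, c("solo", "broad")))
})

test_that("sampling reproduces the brute-force valid set and plants", {
    set.seed(302)
    for (i in 1:5) {
        mat <- randomBinaryDesign(10, 6)
        land <- landscapeFromBinary(mat, "tgt")
        rep <- sampleVEnCodes(land, 3, nSamples = choose(10, 3), seed = 1)
        expect_identical(codeKeys(rep), bruteForceValidSet(mat, "tgt", 3))
    }

    # a single planted triple is found within the sampling budget and the
    # random path is seed-reproducible
    prof <- generateLandscape(10, 22, planted = list(target = "tgt",
                                                     k = 3), seed = 33)
    land <- sparsityFilter(binarizeForTarget(prof, "tgt"), 3)
    rep1 <- sampleVEnCodes(land, 3, nSamples = 10000, seed = 9)
    planted <- plantedCodes(prof)[[1]]$res
    expect_true(paste(sort(planted), collapse = "\r") %in% codeKeys(rep1))
    rep2 <- sampleVEnCodes(land, 3, nSamples = 10000, seed = 9)
    expect_identical(codeKeys(rep1), codeKeys(rep2))

    expect_error(sampleVEnCodes(land, nrow(activityMatrix(land)) + 1L),
                 "fewer than k")
})

test_that("heuristic pads specific REs and descends to blocking pairs", {
    # sparsest RE specific to the target: code = that RE + next 3 sparsest
    mat <- matrix(0, 5, 4, dimnames = list(c("a", "b", "c", "d", "e"),
                                           c("tgt", "n1", "n2", "n3")))
    mat[, "tgt"] <- 1
    mat["b", "n1"] <- 1
    mat["c", c("n1", "n2")] <- 1
    mat["d", c("n1", "n2", "n3")] <- 1
    mat["e", c("n1", "n2", "n3")] <- 1
    land <- landscapeFromBinary(mat, "tgt")
    rep <- heuristicVEnCodes(land, 4, quota = 1)
    expect_equal(reIds(vencodes(rep)[[1]]), c("a", "b", "c", "d"))

    # no single specific RE, but the sparsest-first pair blocks everything
    mat2 <- matrix(c(1, 1, 0,
                     1, 0, 1), 2, 3, byrow = TRUE,
                   dimnames = list(c("x", "y"), c("tgt", "n1", "n2")))
    land2 <- landscapeFromBinary(mat2, "tgt")
    rep2 <- heuristicVEnCodes(land2, 2)
    expect_equal(codeKeys(rep2), paste(sort(c("x", "y")), collapse = "\r"))

    # soundness + coverage against brute force on random landscapes
    set.seed(303)
    nWithCodes <- 0L; nFoundHeu <- 0L
    for (i in 1:100) {
        mat <- randomBinaryDesign(8, 6, pActive = 0.5)
        land <- landscapeFromBinary(mat, "tgt")
        valid <- bruteForceValidSet(mat, "tgt", 3)
        heu <- heuristicVEnCodes(land, 3, quota = 50)
        expect_true(all(codeKeys(heu) %in% valid))
        if (length(valid)) {
            nWithCodes <- nWithCodes + 1L
            if (length(vencodes(heu))) nFoundHeu <- nFoundHeu + 1L
        }
    }
    # the heuristic finds a code for nearly every solvable landscape
    expect_gte(nFoundHeu, 0.9 * nWithCodes)
})

test_that("heuristic2 combines sparsest enhancers with blocking promoters", {
    # enhancers alone suffice: promoter stage skipped, minimal code
    enh <- matrix(c(1, 0, 0,
                    1, 1, 0), 2, 3, byrow = TRUE,
                  dimnames = list(c("e1", "e2"), c("tgt", "n1", "n2")))
    prm <- matrix(c(1, 1, 0), 1, 3,
                  dimnames = list("p1", c("tgt", "n1", "n2")))
    enhL <- landscapeFromBinary(enh, "tgt", reClass = "enhancer",
                                cfg = thresholdConfig("enhancer"))
    prmL <- landscapeFromBinary(prm, "tgt")
    rep <- heuristic2VEnCodes(enhL, prmL, k1 = 1, k2 = 1)
    expect_equal(reIds(vencodes(rep)[[1]]), "e1")
    expect_equal(vencodes(rep)[[1]]@k2, 0L)

    repPad <- heuristic2VEnCodes(enhL, prmL, k1 = 1, k2 = 1,
                                 padToFixed = TRUE)
    expect_length(reIds(vencodes(repPad)[[1]]), 2L)

    # enhancers blocked in exactly one cell type; a promoter resolves it
    enh2 <- matrix(c(1, 1, 0,
                     1, 1, 0), 2, 3, byrow = TRUE,
                   dimnames = list(c("e1", "e2"), c("tgt", "n1", "n2")))
    prm2 <- matrix(c(1, 0, 1), 1, 3,
                   dimnames = list("p1", c("tgt", "n1", "n2")))
    enhL2 <- landscapeFromBinary(enh2, "tgt", reClass = "enhancer",
                                 cfg = thresholdConfig("enhancer"))
    prmL2 <- landscapeFromBinary(prm2, "tgt")
    rep2 <- heuristic2VEnCodes(enhL2, prmL2, k1 = 2, k2 = 1)
    code <- vencodes(rep2)[[1]]
    expect_setequal(reIds(code), c("e1", "e2", "p1"))
    expect_equal(code@k1, 2L)
    expect_equal(code@k2, 1L)
    expect_setequal(reClass(code), c("enhancer", "enhancer", "promoter"))

    # mismatched cell-type universes are an error
    prm3 <- matrix(c(1, 0), 1, 2, dimnames = list("p1", c("tgt", "n9")))
    expect_error(
        heuristic2VEnCodes(enhL2, landscapeFromBinary(prm3, "tgt"),
                           k1 = 2, k2 = 1),
        "cell-type universes")
})

test_that("supersets of a VEnCode drawn from target-active REs stay valid", {
    set.seed(304)
    checked <- 0L
    for (i in 1:30) {
        mat <- randomBinaryDesign(9, 6, pActive = 0.5)
        land <- landscapeFromBinary(mat, "tgt")
        valid2 <- bruteForceValidSet(mat, "tgt", 2)
        if (!length(valid2)) next
        base <- strsplit(valid2[[1]], "\r")[[1]]
        for (extra in setdiff(reIds(land), base)) {
            expect_true(isVEnCode(land, c(base, extra)))
            checked <- checked + 1L
        }
    }
    expect_gt(checked, 20L)
})

test_that("topVEnCodes ranks by E with deterministic tie-breaking", {
    prof <- generateLandscape(8, 16, planted = list(target = "tgt", k = 2),
                              backgroundSparsity = 0.3, seed = 51)
    land <- binarizeForTarget(prof, "tgt")
    repA <- heuristicVEnCodes(land, 2, quota = 4)
    repB <- sampleVEnCodes(land, 3, nSamples = choose(16, 3), quota = 5,
                           seed = 2)
    best <- topVEnCodes(list(repA, repB), 5, land, nSims = 400, seed = 6)
    expect_lte(length(best), 5L)
    es <- vapply(best, eScore, 0)
    expect_true(all(diff(es) <= 1e-9))
    expect_true(all(vapply(best, function(cd)
        isVEnCode(land, cd), TRUE)))

    # stable under report concatenation order
    best2 <- topVEnCodes(list(repB, repA), 5, land, nSims = 400, seed = 6)
    expect_identical(lapply(best, reIds), lapply(best2, reIds))
})

test_that("topVEnCodes breaks exact E ties deterministically by id", {
    # two symmetric target-only REs give identical flip submatrices, hence
    # identical Monte-Carlo scores at a fixed seed: the id order decides
    mat <- matrix(c(1, 0, 0,
                    1, 0, 0,
                    1, 1, 1), 3, 3, byrow = TRUE,
                  dimnames = list(c("b_re", "a_re", "broad"),
                                  c("tgt", "n1", "n2")))
    land <- landscapeFromBinary(mat, "tgt")
    rep <- sampleVEnCodes(land, 1, nSamples = 3)
    best <- topVEnCodes(rep, 2, land, nSims = 200, seed = 4)
    es <- vapply(best, eScore, 0)
    expect_equal(es[[1]], es[[2]])
    expect_equal(unlist(lapply(best, reIds)), c("a_re", "b_re"))
})
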