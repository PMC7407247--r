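test_that("interval overlap follows the half-open, >0-nucleotide rule", {
    iv <- function(chrom, start, end) list(chrom = chrom, start = start,
                                           end = end)
    # 1-nt overlap at the boundary counts; 0-nt (adjacent) does not
    expect_true(intervalsOverlap(iv("chr1", 100, 200), iv("chr1", 199, 300)))
    expect_false(intervalsOverlap(iv("chr1", 100, 200), iv("chr1", 200, 300)))
    expect_true(intervalsOverlap(iv("chr1", 100, 200), iv("chr1", 100, 200)))
    expect_false(intervalsOverlap(iv("chr1", 100, 200), iv("chr2", 100, 200)))
    # "chr1" and "1" are the same chromosome
    expect_true(intervalsOverlap(iv("chr1", 100, 200), iv("1", 150, 160)))
    expect_error(intervalsOverlap(iv("chr1", 200, 100), iv("chr1", 0, 1)),
                 "malformed")

    # symmetry + per-base oracle on random pairs
    set.seed(501)
    for (i in 1:300) {
        a <- iv(sample(c("chr1", "1", "chr2"), 1), s <- sample(0:500, 1),
                s + sample(1:50, 1))
        b <- iv(sample(c("chr1", "1", "chr2"), 1), t <- sample(0:500, 1),
                t + sample(1:50, 1))
        expect_identical(intervalsOverlap(a, b), perBaseOverlap(a, b))
        expect_identical(intervalsOverlap(a, b), intervalsOverlap(b, a))
    }
})

# small landscape whose REs sit at known coordinates (ids embed them)
cvFixture <- function() {
    prof <- generateLandscape(6, 10, planted = list(target = "tgt", k = 3),
                              seed = 61)
    binarizeForTarget(prof, "tgt")
}

test_that("validateCode counts overlapping REs, monotone in the set", {
    land <- cvFixture()
    ids <- reIds(land)[1:4]
    code <- new("VEnCode", target = "tgt", res = ids,
                reClass = rep("promoter", 4), method = "external")
    coords <- as.data.frame(land@intervals[match(ids, reIds(land)), ])

    full <- ExternalRESet(coords, source = "assayA", cellType = "tgt")
    v4 <- validateCode(code, full, land)
    expect_equal(v4@validatedK, 4L)
    expect_equal(v4@fraction, 1)

    half <- ExternalRESet(coords[1:2, ], source = "assayA")
    v2 <- validateCode(code, half, land)
    expect_equal(v2@validatedK, 2L)
    expect_equal(v2@fraction, 0.5)

    none <- ExternalRESet(data.frame(chrom = "chr9", start = 1, end = 2))
    expect_equal(validateCode(code, none, land)@validatedK, 0L)

    # adding intervals never decreases validated_k
    grown <- ExternalRESet(rbind(coords[1:2, ],
                                 data.frame(chrom = "chr9", start = 1,
                                            end = 2)))
    expect_gte(validateCode(code, grown, land)@validatedK, v2@validatedK)
})

test_that("restrictToValidated keeps overlapping REs and is idempotent", {
    land <- cvFixture()
    keep <- reIds(land)[c(1, 3, 5)]
    coords <- as.data.frame(land@intervals[match(keep, reIds(land)), ])
    ext <- ExternalRESet(coords, source = "dhs")

    restricted <- restrictToValidated(land, ext)
    expect_setequal(reIds(restricted), keep)
    twice <- restrictToValidated(restricted, ext)
    expect_identical(activityMatrix(twice), activityMatrix(restricted))

    # searches on the restricted landscape are fully pre-validated
    rep <- heuristicVEnCodes(restricted, 2, quota = 5)
    for (cd in vencodes(rep))
        expect_equal(validateCode(cd, ext, restricted)@fraction, 1)

    faraway <- ExternalRESet(data.frame(chrom = "chrX", start = 0,
                                        end = 10))
    expect_error(restrictToValidated(land, faraway), "no RE")
})

test_that("specificity index flags planted codes above random ones", {
    hits <- c(tgt = 100, a = 50, b = 50)
    expect_equal(specificityIndex(hits, "tgt"), 2)
    expect_equal(specificityIndex(c(tgt = 0, a = 10), "tgt"), 0)
    expect_equal(specificityIndex(c(tgt = 30, a = 30, b = 30), "tgt"), 1)
    expect_identical(specificityIndex(c(tgt = 80, a = 0, b = 0), "tgt"),
                     Inf)
    expect_error(specificityIndex(hits, "absent"), "missing")
    expect_error(specificityIndex(c(tgt = 120, a = 1), "tgt"),
                 "percentages")

    # planted external collection: each cell type's active intervals are
    # exactly its active REs in a synthetic landscape, so true codes hit
    # only the target analogue while random combinations leak
    prof <- generateLandscape(8, 14, planted = list(target = "tgt", k = 3),
                              backgroundSparsity = 0.35, seed = 62)
    land <- binarizeForTarget(prof, "tgt")
    a <- activityMatrix(land)
    coordsOf <- function(ids)
        as.data.frame(land@intervals[match(ids, reIds(land)), ])
    collection <- lapply(cellTypes(land), function(ct) {
        on <- reIds(land)[a[, ct]]
        ExternalRESet(coordsOf(on), source = "sim", cellType = ct)
    })
    names(collection) <- cellTypes(land)

    planted <- plantedCodes(prof)[[1]]$res
    trueCode <- new("VEnCode", target = "tgt", res = planted,
                    reClass = rep("promoter", 3), method = "external")
    set.seed(63)
    randomCodes <- lapply(1:20, function(i)
        new("VEnCode", target = "tgt",
            res = sample(reIds(land), 3),
            reClass = rep("promoter", 3), method = "external"))

    hitsTrue <- matchCodesAcrossDatabase(list(trueCode), collection, land)
    hitsRand <- matchCodesAcrossDatabase(randomCodes, collection, land)
    expect_equal(unname(hitsTrue[["tgt"]]), 100)
    # the planted code hits no non-target analogue; random ones leak more
    siTrue <- specificityIndex(hitsTrue, "tgt")
    siRand <- specificityIndex(hitsRand, "tgt")
    expect_true(is.infinite(siTrue) || siTrue > siRand)
    # random combinations hit non-targets at least as often as true codes
    nt <- setdiff(names(hitsRand), "tgt")
    expect_gte(mean(hitsRand[nt]), mean(hitsTrue[nt]))
})
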