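# Independent oracles and fixture builders.  These deliberately avoid the
# package's own code paths so they can serve as ground truth.

# Build donor-level profiles from a TPM matrix (colnames "cellType, donor"
# are derived from the two vectors).
makeProfiles <- function(x, cellType, donor, reClass = "promoter") {
    RegulatoryProfiles(x, cellType, donor, reClass = reClass)
}

# Build a BinaryLandscape from a 0/1 design matrix through the real
# binarization path: one donor per cell type, TPM 1 for active entries
# (above the 0.5 promoter threshold), 0 otherwise.
landscapeFromBinary <- function(mat, target, reClass = "promoter",
                                cfg = NULL) {
    storage.mode(mat) <- "double"
    if (is.null(rownames(mat)))
        rownames(mat) <- sprintf("re%02d", seq_len(nrow(mat)))
    prof <- RegulatoryProfiles(mat, colnames(mat),
                               rep("donor1", ncol(mat)),
                               reClass = reClass)
    binarizeForTarget(prof, target, cfg)
}

# Random binary design with every RE active in the target and at least one
# inactive RE per non-target column not guaranteed (that is the point).
randomBinaryDesign <- function(r, c, target = "tgt", pActive = 0.4) {
    mat <- matrix(runif(r * c) < pActive, r, c)
    mat[, 1L] <- TRUE
    colnames(mat) <- c(target, sprintf("nt%02d", seq_len(c - 1L)))
    rownames(mat) <- sprintf("re%02d", seq_len(r))
    mat + 0
}

# Truth-table oracle for exclusivity: direct evaluation of the
# conjunctive-normal-form condition (all REs active in the target AND, for
# every other cell type, NOT all REs active), written against the raw 0/1
# matrix with no package calls.
cnfExclusive <- function(mat, target, res) {
    sub <- mat[res, , drop = FALSE] > 0
    if (!all(sub[, target])) return(FALSE)
    for (ct in setdiff(colnames(mat), target))
        if (all(sub[, ct])) return(FALSE)
    TRUE
}

# Brute-force valid set: all C(r, k) combinations passing the CNF oracle,
# as a sorted character vector of canonical keys.
bruteForceValidSet <- function(mat, target, k) {
    ids <- rownames(mat)
    keys <- character()
    for (res in utils::combn(ids, k, simplify = FALSE))
        if (cnfExclusive(mat, target, res))
            keys <- c(keys, paste(sort(res), collapse = "\r"))
    sort(keys)
}

codeKeys <- function(codes) {
    if (is(codes, "SearchReport")) codes <- vencodes(codes)
    sort(vapply(codes, function(cd)
        paste(sort(reIds(cd)), collapse = "\r"), ""))
}

# Exact expectation of the flip count until some column is fully active,
# when the initially-inactive entries are flipped in uniformly random
# order.  colSizes gives the number of initially-inactive entries per
# non-target column (every entry belongs to exactly one column).  By
# inclusion-exclusion over the set of completed columns,
#   P(e > t) = sum_T (-1)^|T| C(m - s_T, t - s_T) / C(m, t),
# and E[e] = sum_{t >= 0} P(e > t).
exactExpectedFlips <- function(colSizes) {
    stopifnot(all(colSizes >= 1))
    m <- sum(colSizes)
    nc <- length(colSizes)
    pGreater <- function(t) {
        total <- 0
        for (sz in 0:nc) {
            subs <- if (sz == 0) list(integer()) else
                utils::combn(nc, sz, simplify = FALSE)
            for (T in subs) {
                sT <- sum(colSizes[T])
                if (t >= sT)
                    total <- total + (-1)^sz * choose(m - sT, t - sT)
            }
        }
        total / choose(m, t)
    }
    sum(vapply(0:(m - 1L), pGreater, 0))
}

# Per-base overlap oracle: explicit shared-nucleotide count between two
# 0-based half-open intervals.
perBaseOverlap <- function(a, b) {
    if (sub("^chr", "", a$chrom) != sub("^chr", "", b$chrom)) return(FALSE)
    basesA <- seq(a$start, a$end - 1L)
    basesB <- seq(b$start, b$end - 1L)
    length(intersect(basesA, basesB)) > 0L
}

# Exhaustive z recomputation for toy tables: for every train subset of the
# given size, regenerate codes and check each held-out donor directly
# against the raw TPM.
zOracle <- function(prof, targetCT, trainSize, k, nSamples = 10000) {
    cd <- as.data.frame(SummarizedExperiment::colData(prof))
    donors <- cd$donor[cd$cellType == targetCT]
    x <- SummarizedExperiment::assay(prof, "tpm")
    zs <- c()
    for (train in utils::combn(donors, trainSize, simplify = FALSE)) {
        held <- setdiff(donors, train)
        keep <- !(cd$cellType == targetCT & !(cd$donor %in% train))
        land <- tryCatch(binarizeForTarget(prof[, keep], targetCT),
                         error = function(e) NULL)
        if (is.null(land)) { zs <- c(zs, NA); next }
        fl <- tryCatch(sparsityFilter(land, k), error = function(e) land)
        rep <- sampleVEnCodes(fl, k, nSamples = nSamples, seed = 1)
        codes <- vencodes(rep)
        if (!length(codes)) { zs <- c(zs, NA); next }
        ok <- vapply(codes, function(cdE) {
            cols <- paste(targetCT, held, sep = ", ")
            all(x[reIds(cdE), cols, drop = FALSE] > 0.5)
        }, TRUE)
        zs <- c(zs, 100 * mean(ok))
    }
    zs
}
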