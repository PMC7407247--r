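#' @include search.R
NULL

# The Monte-Carlo flip process: entries of the code's k x (c-1) non-target
# submatrix that are inactive get flipped on one at a time, uniformly at
# random without repetition, until some non-target column becomes fully
# active (the code stops being exclusive).  Choosing uniformly among the
# currently-inactive entries at every step is equivalent to flipping the
# initially-inactive entries in a uniformly random order, so each
# simulation draws one permutation and reads off the first time any
# column's inactive entries are exhausted.
simulateFlips <- function(inactiveCol, nSims) {
    m <- length(inactiveCol)
    bycol <- split(seq_len(m), inactiveCol)
    vapply(seq_len(nSims), function(i) {
        pos <- sample.int(m)
        min(vapply(bycol, function(ii) max(pos[ii]), 0L))
    }, 0L)
}

#' Monte-Carlo intraindividual robustness E_raw of a VEnCode
#'
#' Simulates database false negatives: random inactive-to-active flips in
#' the code's k x (c-1) non-target submatrix, one at a time, until the code
#' stops being exclusive; E_raw is the mean flip count over \code{nSims}
#' simulations.  Flips outside the code's own submatrix can never change
#' its validity, so the flip universe is restricted to the submatrix; the
#' restriction rescales E_raw identically for a code and its best-case
#' reference and therefore leaves the normalized E unchanged.
#'
#' @param landscape the \linkS4class{BinaryLandscape} the code lives in.
#' @param code a \linkS4class{VEnCode} or character vector of RE ids; must
#'   be valid in \code{landscape}.
#' @param nSims number of simulations (default 2000).
#' @param seed RNG seed.
#' @return an unnormalized \linkS4class{QualityScore} (eBest/e are NA until
#'   [normalizeE()]).
#' @export
eRaw <- function(landscape, code, nSims = 2000L, seed = NULL) {
    ids <- if (is(code, "VEnCode")) code@res else code
    if (!isVEnCode(landscape, ids))
        stop("code is not a valid VEnCode in this landscape; E is undefined")
    a <- landscape@active
    nt <- setdiff(colnames(a), landscape@target)
    sub <- a[ids, nt, drop = FALSE]
    inactive <- which(!sub, arr.ind = TRUE)
    flips <- withSeed(seed, simulateFlips(inactive[, "col"],
                                          as.integer(nSims)))
    new("QualityScore", eRaw = mean(flips), nSims = as.integer(nSims),
        perSimFlips = as.numeric(flips),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

.eBestCache <- new.env(parent = emptyenv())

#' Best-case reference E_best(c, k)
#'
#' E_raw of a best-case code: all k REs inactive in every one of the c - 1
#' non-target cell types.  Obtained by the same Monte-Carlo simulation on an
#' all-inactive k x (c-1) submatrix, and memoized per (c, k, nSims, seed).
#'
#' @param c number of cell types (including the target).
#' @param k code size.
#' @param nSims number of simulations (default 2000).
#' @param seed RNG seed.
#' @return the mean flip count for the best-case code.
#' @export
eBest <- function(c, k, nSims = 2000L, seed = NULL) {
    stopifnot(c >= 2L, k >= 1L)
    key <- paste(c, k, nSims, if (is.null(seed)) "NULL" else seed,
                 sep = "|")
    if (!is.null(.eBestCache[[key]])) return(.eBestCache[[key]])
    inactiveCol <- rep(seq_len(c - 1L), each = k)
    val <- mean(withSeed(seed, simulateFlips(inactiveCol,
                                             as.integer(nSims))))
    .eBestCache[[key]] <- val
    val
}

#' Normalize an E_raw score to the E scale
#'
#' E = 100 * E_raw / E_best(c, k); best-case codes score ~100, and E is
#' scale-comparable across landscapes of different size and codes of
#' different k.  Monte-Carlo noise can push E slightly above 100; such
#' values are reported as-is with a warning rather than clamped, since
#' clamping would bias rank comparisons.
#'
#' @param score an unnormalized \linkS4class{QualityScore} from [eRaw()].
#' @param c number of cell types of the landscape the score was computed
#'   in.
#' @param k code size.
#' @param nSims simulations for the reference (defaults to the score's).
#' @param seed RNG seed for the reference simulations.
#' @return the \linkS4class{QualityScore} with \code{eBest} and \code{e}
#'   filled in.
#' @export
normalizeE <- function(score, c, k, nSims = score@nSims, seed = NULL) {
    eb <- eBest(c, k, nSims = nSims, seed = seed)
    stopifnot(eb > 0)
    score@eBest <- eb
    score@e <- 100 * score@eRaw / eb
    if (score@e > 100 + 1e-9)
        warning(sprintf("E = %.2f exceeds 100 (Monte-Carlo noise)",
                        score@e))
    score
}

#' Score a VEnCode: E_raw plus normalized E in one call
#'
#' @inheritParams eRaw
#' @return a normalized \linkS4class{QualityScore}.
#' @export
scoreVEnCode <- function(landscape, code, nSims = 2000L, seed = NULL) {
    q <- eRaw(landscape, code, nSims = nSims, seed = seed)
    ids <- if (is(code, "VEnCode")) code@res else code
    normalizeE(q, c = ncol(landscape@active), k = length(ids), seed = seed)
}

#' Standard error of a Monte-Carlo E_raw estimate
#'
#' @param score a \linkS4class{QualityScore}.
#' @return sd(per-simulation flips) / sqrt(nSims).
#' @export
eStandardError <- function(score) {
    stats::sd(score@perSimFlips) / sqrt(score@nSims)
}

#' Interindividual robustness z by donor hold-out
#'
#' Builds a landscape using only a subset of the target's donors, generates
#' VEnCodes from it, and tests every code on each held-out donor: a donor
#' satisfies a code iff all its REs exceed the activity threshold in that
#' donor's raw TPM profile.  z is the percentage of codes that satisfy
#' every held-out donor.  With \code{trainSize} given instead of
#' \code{donorsTrain}, all training subsets of that size are evaluated and
#' the per-subset z values are averaged.
#'
#' @param profiles the donor-level \linkS4class{RegulatoryProfiles}.
#' @param targetCellType the target cell type (needs >= 2 donors).
#' @param donorsTrain explicit training-donor subset (proper, nonempty), or
#'   NULL to use \code{trainSize}.
#' @param trainSize size of the training subsets to evaluate.
#' @param method "sampling" or "heuristic" code generation.
#' @param k code size (default 4).
#' @param cfg \linkS4class{ThresholdConfig}; defaults by RE class.
#' @param nSamples sampling budget (sampling method).
#' @param quota maximum codes per subset (default 20).
#' @param seed RNG seed.
#' @return a \linkS4class{RobustnessScore}; subsets where no code could be
#'   generated contribute NA and are dropped from the mean.
#' @export
donorHoldOutZ <- function(profiles, targetCellType, donorsTrain = NULL,
                          trainSize = NULL,
                          method = c("sampling", "heuristic"), k = 4L,
                          cfg = NULL, nSamples = 1000L, quota = 20L,
                          seed = NULL) {
    method <- match.arg(method)
    cd <- colData(profiles)
    donors <- as.character(cd$donor[cd$cellType == targetCellType])
    if (length(donors) < 2L)
        stop("target '", targetCellType, "' has fewer than 2 donors; ",
             "z is undefined")
    subsets <- if (!is.null(donorsTrain)) {
        donorsTrain <- as.character(donorsTrain)
        if (!all(donorsTrain %in% donors) ||
            length(donorsTrain) >= length(donors) || !length(donorsTrain))
            stop("donorsTrain must be a proper nonempty subset of the ",
                 "target's donors")
        list(donorsTrain)
    } else {
        stopifnot(!is.null(trainSize), trainSize >= 1L,
                  trainSize < length(donors))
        utils::combn(donors, trainSize, simplify = FALSE)
    }
    x <- tpm(profiles)
    perZ <- rep(NA_real_, length(subsets))
    nTested <- 0L
    for (si in seq_along(subsets)) {
        train <- subsets[[si]]
        held <- setdiff(donors, train)
        dropCols <- cd$cellType == targetCellType & !(cd$donor %in% train)
        trainProf <- profiles[, !dropCols]
        land <- tryCatch(binarizeForTarget(trainProf, targetCellType, cfg),
                         error = function(e) NULL)
        if (is.null(land)) next
        report <- if (method == "sampling") {
            fl <- tryCatch(sparsityFilter(land, k),
                           error = function(e) land)
            if (nrow(fl@active) < k) next
            sampleVEnCodes(fl, k, nSamples = nSamples, quota = quota,
                           seed = if (is.null(seed)) NULL else seed + si)
        } else heuristicVEnCodes(land, k, quota = quota)
        codes <- vencodes(report)
        if (!length(codes)) next
        thr <- land@thresholds
        heldCols <- sampleLabel(targetCellType, held)
        ok <- vapply(codes, function(cdE) {
            sub <- x[cdE@res, heldCols, drop = FALSE]
            all(exceeds(sub, thr@activityTarget, thr@strict))
        }, TRUE)
        perZ[si] <- 100 * mean(ok)
        nTested <- nTested + length(codes)
    }
    if (all(is.na(perZ)))
        warning("no VEnCodes could be generated from any training subset; ",
                "z is undefined")
    new("RobustnessScore", z = mean(perZ, na.rm = TRUE), perSubsetZ = perZ,
        donorsTrain = subsets, nCodesTested = nTested)
}
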