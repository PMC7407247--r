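#' @include single-cell.R
NULL

#' Generate a synthetic RE landscape with planted ground-truth codes
#'
#' Emulates the structure of a curated CAGE-seq atlas: c cell types with
#' 2-6 donors each, r target-active candidate REs, sparse background
#' activity, and log-normal TPM values for active entries.  Ground-truth
#' codes are planted so that they are valid by construction: for every
#' non-target cell type at least one planted RE is forced inactive (the
#' "alibi" pattern), with all remaining entries Bernoulli background.  With
#' \code{uniquePlant = TRUE} (default, single plant only) one "signature"
#' non-target cell type per planted RE is additionally patterned so that
#' the planted RE is its only blocker, which makes the planted set the
#' unique valid code of size <= k pre-noise.
#'
#' RE ids embed synthetic coordinates ("chr1:start-end"), so interval-based
#' cross-validation can run on generated data.
#'
#' @param nCellTypes number of cell types (c).
#' @param nREs number of REs (r); all are active in planted target cell
#'   types (the generator models the target-active candidate pool).
#' @param donorsPerType integer vector of admissible donor counts per cell
#'   type (default 2:6); each cell type draws one.
#' @param planted list of plants, each \code{list(target =, k =)} or
#'   \code{list(target =, res = <RE indices or ids>)}; targets must be
#'   distinct and plants use disjoint REs.
#' @param backgroundSparsity per-entry background activation probability in
#'   non-target cell types (default 0.2).
#' @param tpmMeanlog,tpmSdlog log-normal parameters for active TPM values
#'   (default meanlog 0, sdlog 1).
#' @param tpmShift constant added to active TPM draws so active entries
#'   clear the activity threshold (default 0.5).
#' @param fnRate,fpRate false-negative / false-positive corruption rates
#'   applied per donor-level entry after construction (default 0).
#' @param reClass RE class label for all rows (default "promoter").
#' @param uniquePlant pattern signature columns so a single planted code is
#'   the unique minimal valid code pre-noise (default TRUE; ignored with a
#'   warning when several plants are given).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return a \linkS4class{RegulatoryProfiles} whose \code{metadata} records
#'   the planted codes (\code{metadata(x)$planted}), the seed, and the
#'   generator settings.
#' @export
generateLandscape <- function(nCellTypes, nREs, donorsPerType = 2:6,
                              planted = list(),
                              backgroundSparsity = 0.2,
                              tpmMeanlog = 0, tpmSdlog = 1, tpmShift = 0.5,
                              fnRate = 0, fpRate = 0,
                              reClass = "promoter", uniquePlant = TRUE,
                              seed = NULL) {
    stopifnot(nCellTypes >= 2L, nREs >= 1L,
              backgroundSparsity >= 0, backgroundSparsity <= 1,
              fnRate >= 0, fnRate <= 1, fpRate >= 0, fpRate <= 1)
    if (length(planted) && !is.null(planted$target))
        planted <- list(planted)     # single plant given unnested
    targets <- vapply(planted, function(p) p$target, "")
    if (anyDuplicated(targets))
        stop("planted targets must be distinct")
    if (length(planted) > 1L && uniquePlant) {
        warning("uniquePlant applies to single-plant specs only; disabled")
        uniquePlant <- FALSE
    }
    cts <- unique(c(targets,
                    sprintf("ct%02d", seq_len(nCellTypes))))[
                        seq_len(nCellTypes)]
    if (!all(targets %in% cts))
        stop("more planted targets than cell types")
    ids <- sprintf("chr1:%d-%d", 1000L * seq_len(nREs),
                   1000L * seq_len(nREs) + 500L)

    withSeed(seed, {
        # resolve planted RE sets (disjoint across plants)
        used <- integer()
        plants <- lapply(planted, function(p) {
            if (!is.null(p$res)) {
                idx <- if (is.character(p$res)) match(p$res, ids)
                       else as.integer(p$res)
            } else {
                stopifnot(!is.null(p$k))
                if (p$k > nREs - length(used))
                    stop("infeasible plant: k exceeds available REs")
                idx <- sample(setdiff(seq_len(nREs), used), p$k)
            }
            if (anyNA(idx) || anyDuplicated(idx) ||
                length(intersect(idx, used)))
                stop("infeasible plant: bad or reused RE ids")
            used <<- c(used, idx)
            list(target = p$target, idx = sort(idx))
        })

        # per-cell-type activity design
        active <- matrix(stats::runif(nREs * nCellTypes) <
                             backgroundSparsity,
                         nREs, nCellTypes, dimnames = list(ids, cts))
        for (pl in plants) active[, pl$target] <- TRUE
        forcedActive <- matrix(FALSE, nREs, nCellTypes,
                               dimnames = list(ids, cts))
        for (pl in plants) {
            nt <- setdiff(cts, pl$target)
            k <- length(pl$idx)
            if (uniquePlant) {
                if (length(nt) < k)
                    stop("uniquePlant needs at least k non-target cell ",
                         "types")
                sig <- sample(nt, k)
                for (i in seq_len(k)) {
                    active[, sig[i]] <- TRUE       # everyone else active
                    active[pl$idx[i], sig[i]] <- FALSE  # sole blocker
                    forcedActive[-pl$idx[i], sig[i]] <- TRUE
                }
            }
            # alibi repair: every non-target cell type must be blocked by
            # at least one planted RE
            for (j in nt) {
                blockers <- !active[pl$idx, j]
                if (!any(blockers)) {
                    free <- pl$idx[!forcedActive[pl$idx, j]]
                    if (!length(free)) next  # conflicting plant; skip
                    active[sample(free, 1L), j] <- FALSE
                }
            }
        }

        # donors and TPM values
        nd <- sample(rep(donorsPerType, length.out = max(nCellTypes,
                                                         length(donorsPerType))),
                     nCellTypes, replace = TRUE)
        cellType <- rep(cts, nd)
        donor <- unlist(lapply(nd, function(n) sprintf("donor%d",
                                                       seq_len(n))))
        x <- matrix(0, nREs, length(cellType),
                    dimnames = list(ids, NULL))
        for (jj in seq_along(cellType)) {
            on <- active[, cellType[jj]]
            x[on, jj] <- tpmShift +
                stats::rlnorm(sum(on), tpmMeanlog, tpmSdlog)
        }
        prof <- RegulatoryProfiles(x, cellType, donor, reClass = reClass)
        metadata(prof)$planted <- lapply(plants, function(pl)
            list(target = pl$target, res = ids[pl$idx]))
        metadata(prof)$seed <- seed
        metadata(prof)$generator <- list(
            nCellTypes = nCellTypes, nREs = nREs,
            donorsPerType = donorsPerType,
            backgroundSparsity = backgroundSparsity,
            tpmMeanlog = tpmMeanlog, tpmSdlog = tpmSdlog,
            tpmShift = tpmShift, fnRate = fnRate, fpRate = fpRate,
            uniquePlant = uniquePlant)
        if (fnRate > 0 || fpRate > 0)
            prof <- corruptProfiles(prof, fnRate, fpRate)
        prof
    })
}

#' Planted ground-truth codes of a synthetic landscape
#'
#' @param profiles a \linkS4class{RegulatoryProfiles} from
#'   [generateLandscape()].
#' @return list of \code{list(target, res)} ground-truth codes.
#' @export
plantedCodes <- function(profiles) metadata(profiles)$planted

#' Corrupt a profile set with false negatives and false positives
#'
#' Independently zeroes active (TPM > 0) donor-level entries with
#' probability \code{fnRate} and activates inactive entries at a sentinel
#' TPM with probability \code{fpRate}.
#'
#' @param profiles a \linkS4class{RegulatoryProfiles}.
#' @param fnRate,fpRate corruption probabilities in [0, 1].
#' @param seed RNG seed (NULL: use the current RNG stream).
#' @param sentinelTPM TPM for falsely activated entries (default 10).
#' @return the corrupted \linkS4class{RegulatoryProfiles}.
#' @export
corruptProfiles <- function(profiles, fnRate, fpRate, seed = NULL,
                            sentinelTPM = 10) {
    stopifnot(fnRate >= 0, fnRate <= 1, fpRate >= 0, fpRate <= 1)
    x <- tpm(profiles)
    wasActive <- x > 0
    withSeed(seed, {
        u <- matrix(stats::runif(length(x)), nrow(x))
        x[wasActive & u < fnRate] <- 0
        x[!wasActive & u < fpRate] <- sentinelTPM
    })
    out <- profiles
    assays(out)$tpm <- x
    validObject(out)
    out
}

#' Write the ground truth of a synthetic landscape as JSON
#'
#' @param profiles a \linkS4class{RegulatoryProfiles} from
#'   [generateLandscape()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(profiles, path) {
    jsonlite::write_json(
        list(planted = plantedCodes(profiles),
             seed = metadata(profiles)$seed,
             generator = metadata(profiles)$generator),
        path, auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
}
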