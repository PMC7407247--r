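#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- colData colData<- rowData rowData<-
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom S4Vectors DataFrame
NULL

#' RegulatoryProfiles: an RE-by-sample TPM activity matrix
#'
#' The central raw-data container: a \linkS4class{SummarizedExperiment} whose
#' single \code{"tpm"} assay holds non-negative TPM values for regulatory
#' elements (rows; promoters or enhancers) across samples (columns).  Each
#' sample is a (cell type, donor) pair recorded in \code{colData}; each RE
#' carries its class and, when known, genomic coordinates (0-based half-open,
#' BED convention) in \code{rowData} columns \code{chrom}/\code{start}/
#' \code{end}.
#'
#' Invariants enforced by the validity method: unique RE ids (rownames),
#' unique (cellType, donor) pairs, and finite, non-negative TPM values.
#'
#' @seealso [readExpressionTable()], [curateProfiles()], [binarizeForTarget()]
#' @export
setClass("RegulatoryProfiles", contains = "SummarizedExperiment")

setValidity("RegulatoryProfiles", function(object) {
    msg <- NULL
    if (!"tpm" %in% names(assays(object)))
        msg <- c(msg, "assay 'tpm' is required")
    else {
        x <- assay(object, "tpm")
        if (is.null(rownames(object)))
            msg <- c(msg, "RE ids (rownames) are required")
        else if (anyDuplicated(rownames(object)))
            msg <- c(msg, sprintf("duplicated RE id(s): %s",
                paste(unique(rownames(object)[duplicated(rownames(object))]),
                      collapse = ", ")))
        if (any(!is.finite(x)) || any(x < 0))
            msg <- c(msg, "TPM values must be finite and >= 0")
    }
    cd <- colData(object)
    if (!all(c("cellType", "donor") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'cellType' and 'donor'")
    else if (anyDuplicated(paste(cd$cellType, cd$donor, sep = "\r")))
        msg <- c(msg, "duplicated (cellType, donor) sample pairs")
    rd <- rowData(object)
    if ("reClass" %in% colnames(rd) &&
        !all(rd$reClass %in% c("promoter", "enhancer", NA_character_)))
        msg <- c(msg, "reClass must be 'promoter' or 'enhancer'")
    if (is.null(msg)) TRUE else msg
})

#' ThresholdConfig: binarization thresholds and sparsity-filter settings
#'
#' Holds the conservative activity criteria used to binarize a TPM landscape
#' for one target cell type, plus the settings of the sparse-RE pre-filter.
#'
#' @slot activityTarget TPM threshold every target donor must exceed for an
#'   RE to count as active in the target (default 0.5 for promoters, 0.1 for
#'   enhancers).
#' @slot inactivityNonTarget TPM threshold the donor-mean of a non-target
#'   cell type must exceed to be called active there (default 0).
#' @slot nonzeroPrefilter REs must exceed this TPM in all target donors to be
#'   retained at all (default 0, the "potentially ON in all donors" rule).
#' @slot sparsityStartPct starting X of the sparsity filter: REs active in
#'   more than X percent of non-target cell types are removed (default 90).
#' @slot sparsityStep step by which X moves when fewer than k REs survive
#'   (default 5).
#' @slot sparsityDirection "decrement" (lower X each retry, the literal
#'   published reading) or "increment" (relax the filter each retry, which is
#'   the direction that can actually recover more REs); see the package
#'   vignette for why both readings are offered.
#' @slot strict logical; TRUE compares with ">" (thresholds are exceeded,
#'   the default), FALSE with ">=".
#' @export
setClass("ThresholdConfig",
    representation(activityTarget = "numeric",
                   inactivityNonTarget = "numeric",
                   nonzeroPrefilter = "numeric",
                   sparsityStartPct = "numeric",
                   sparsityStep = "numeric",
                   sparsityDirection = "character",
                   strict = "logical"))

setValidity("ThresholdConfig", function(object) {
    msg <- NULL
    if (object@activityTarget <= object@inactivityNonTarget)
        msg <- c(msg, "activityTarget must exceed inactivityNonTarget")
    if (object@inactivityNonTarget < 0)
        msg <- c(msg, "inactivityNonTarget must be >= 0")
    if (object@sparsityStartPct <= 0 || object@sparsityStartPct > 100)
        msg <- c(msg, "sparsityStartPct must be in (0, 100]")
    if (object@sparsityStep <= 0)
        msg <- c(msg, "sparsityStep must be > 0")
    if (!object@sparsityDirection %in% c("decrement", "increment"))
        msg <- c(msg, "sparsityDirection must be 'decrement' or 'increment'")
    if (is.null(msg)) TRUE else msg
})

#' BinaryLandscape: a per-target binarized RE-by-cell-type activity matrix
#'
#' The result of [binarizeForTarget()]: a logical r x c matrix whose columns
#' are the target cell type plus every (donor-collapsed) non-target cell
#' type.  By construction every retained RE is active in the target column.
#'
#' @slot target the target cell type (one of \code{colnames(active)}).
#' @slot active logical r x c activity matrix; rownames are RE ids.
#' @slot reClass character vector ("promoter"/"enhancer"/NA) per RE row.
#' @slot intervals \code{DataFrame} with chrom/start/end per RE (NA when
#'   coordinates are unknown; 0-based half-open).
#' @slot thresholds the \linkS4class{ThresholdConfig} used.
#' @export
setClass("BinaryLandscape",
    representation(target = "character",
                   active = "matrix",
                   reClass = "character",
                   intervals = "DataFrame",
                   thresholds = "ThresholdConfig"))

setValidity("BinaryLandscape", function(object) {
    msg <- NULL
    a <- object@active
    if (!is.logical(a))
        msg <- c(msg, "active must be a logical matrix")
    if (nrow(a) < 1L || ncol(a) < 2L)
        msg <- c(msg, "landscape needs r >= 1 REs and c >= 2 cell types")
    if (!object@target %in% colnames(a))
        msg <- c(msg, "target must be a column of the activity matrix")
    else if (!all(a[, object@target]))
        msg <- c(msg, "every RE must be active in the target column")
    if (is.null(rownames(a)) || anyDuplicated(rownames(a)))
        msg <- c(msg, "RE ids (rownames) must be present and unique")
    if (length(object@reClass) != nrow(a))
        msg <- c(msg, "reClass must have one entry per RE")
    if (is.null(msg)) TRUE else msg
})

#' VEnCode: an ordered set of k REs exclusive to one target cell type
#'
#' A versatile entry code: k regulatory elements, all active in the target
#' cell type, such that in every other cell type at least one member is
#' inactive ("AND"-gate exclusivity).
#'
#' @slot target target cell type.
#' @slot res ordered character vector of k distinct RE ids.
#' @slot reClass "promoter"/"enhancer"/NA per RE.
#' @slot method one of "sampling", "heuristic", "heuristic2", "external".
#' @slot k1,k2 for mixed-class codes: number of enhancers (k1) and promoters
#'   (k2); NA otherwise.
#' @slot quality optional \linkS4class{QualityScore} attached by ranking.
#' @export
setClass("VEnCode",
    representation(target = "character",
                   res = "character",
                   reClass = "character",
                   method = "character",
                   k1 = "integer",
                   k2 = "integer",
                   quality = "ANY"),
    prototype(k1 = NA_integer_, k2 = NA_integer_, quality = NULL))

setValidity("VEnCode", function(object) {
    msg <- NULL
    if (length(object@res) < 1L)
        msg <- c(msg, "a VEnCode needs k >= 1 REs")
    if (anyDuplicated(object@res))
        msg <- c(msg, "RE ids within a VEnCode must be distinct")
    if (length(object@reClass) != length(object@res))
        msg <- c(msg, "reClass must match res in length")
    if (!object@method %in% c("sampling", "heuristic", "heuristic2",
                              "external"))
        msg <- c(msg, "unknown source method")
    if (is.null(msg)) TRUE else msg
})

#' SearchReport: the outcome of one VEnCode search
#'
#' @slot target target cell type.
#' @slot method search method used.
#' @slot k requested code size (total size for heuristic2).
#' @slot nIterations number of combinations drawn/visited.
#' @slot vencodes list of \linkS4class{VEnCode} found (possibly empty).
#' @slot seed the RNG seed used (NA for deterministic searches).
#' @export
setClass("SearchReport",
    representation(target = "character",
                   method = "character",
                   k = "integer",
                   nIterations = "integer",
                   vencodes = "list",
                   seed = "integer"),
    prototype(seed = NA_integer_))

#' QualityScore: Monte-Carlo intraindividual robustness of a VEnCode
#'
#' E_raw is the mean number of random false-negative corrections (0-to-1
#' flips in the code's non-target submatrix) the code withstands before it
#' stops being exclusive; E_best(c, k) is the same quantity for a best-case
#' code with the same dimensions; E = 100 * E_raw / E_best.
#'
#' @slot eRaw mean flip count to failure.
#' @slot eBest best-case reference value (NA until normalized).
#' @slot e normalized score (NA until normalized).
#' @slot nSims number of Monte-Carlo simulations.
#' @slot perSimFlips integer vector of per-simulation flip counts.
#' @slot seed RNG seed used.
#' @export
setClass("QualityScore",
    representation(eRaw = "numeric",
                   eBest = "numeric",
                   e = "numeric",
                   nSims = "integer",
                   perSimFlips = "numeric",
                   seed = "integer"),
    prototype(eBest = NA_real_, e = NA_real_, seed = NA_integer_))

setValidity("QualityScore", function(object) {
    msg <- NULL
    if (length(object@perSimFlips) &&
        (object@eRaw < 1 || any(object@perSimFlips < 1)))
        msg <- c(msg, "at least one flip is needed to break a valid code")
    if (is.null(msg)) TRUE else msg
})

#' RobustnessScore: donor hold-out (interindividual) robustness z
#'
#' @slot z percentage (0-100) of codes built from the training donors that
#'   remain valid on every held-out donor (mean over train subsets when
#'   several were evaluated).
#' @slot perSubsetZ per-train-subset z values.
#' @slot donorsTrain list of training-donor subsets evaluated.
#' @slot nCodesTested total number of codes tested.
#' @export
setClass("RobustnessScore",
    representation(z = "numeric",
                   perSubsetZ = "numeric",
                   donorsTrain = "list",
                   nCodesTested = "integer"))

setValidity("RobustnessScore", function(object) {
    if (!is.na(object@z) && (object@z < 0 || object@z > 100))
        "z must be a percentage in [0, 100]" else TRUE
})

#' ExternalRESet: regulatory-element intervals from an independent assay
#'
#' Genomic intervals (DNase, ATAC-seq, STARR-seq, ChIP, ...) called active
#' in one cell type, used to cross-validate CAGE-seq-derived codes.
#' Duplicate intervals are collapsed on construction; strand is ignored.
#'
#' @slot source free-text assay/study tag.
#' @slot cellType cell type the calls refer to.
#' @slot intervals a \linkS4class{GRanges} of the calls.
#' @export
setClass("ExternalRESet",
    representation(source = "character",
                   cellType = "character",
                   intervals = "GRanges"))

#' PooledProfile: single-cell "ON" calls pooled into one binary profile
#'
#' @slot cellType label for the pooled population.
#' @slot nCells number of single cells pooled.
#' @slot onREs union of the per-cell "ON" RE ids; every RE not listed is
#'   OFF by definition.
#' @export
setClass("PooledProfile",
    representation(cellType = "character",
                   nCells = "integer",
                   onREs = "character"))

setValidity("PooledProfile", function(object) {
    if (object@nCells < 1L) "nCells must be >= 1" else TRUE
})
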