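#' @include AllClasses.R
NULL

#' Accessors for VEnCodeR classes
#'
#' Small accessor generics used throughout the package instead of direct
#' slot access.
#'
#' @param x an object.
#' @return \code{tpm}: the TPM matrix; \code{cellTypes}: character vector of
#'   cell types; \code{reIds}: RE identifiers; \code{reClass}: RE classes;
#'   \code{activityMatrix}: the logical RE x cell-type matrix;
#'   \code{target}: the target cell type; \code{vencodes}: list of codes in
#'   a report; \code{eScore}: the normalized E value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))

#' @rdname accessors
#' @export
setMethod("tpm", "RegulatoryProfiles", function(x) assay(x, "tpm"))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setMethod("cellTypes", "RegulatoryProfiles",
    function(x) unique(as.character(colData(x)$cellType)))

#' @rdname accessors
#' @export
setMethod("cellTypes", "BinaryLandscape", function(x) colnames(x@active))

#' @rdname accessors
#' @export
setGeneric("reIds", function(x) standardGeneric("reIds"))

#' @rdname accessors
#' @export
setMethod("reIds", "RegulatoryProfiles", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("reIds", "BinaryLandscape", function(x) rownames(x@active))

#' @rdname accessors
#' @export
setMethod("reIds", "VEnCode", function(x) x@res)

#' @rdname accessors
#' @export
setGeneric("reClass", function(x) standardGeneric("reClass"))

#' @rdname accessors
#' @export
setMethod("reClass", "RegulatoryProfiles", function(x) {
    rd <- rowData(x)
    if ("reClass" %in% colnames(rd)) as.character(rd$reClass)
    else rep(NA_character_, nrow(x))
})

#' @rdname accessors
#' @export
setMethod("reClass", "BinaryLandscape", function(x) x@reClass)

#' @rdname accessors
#' @export
setMethod("reClass", "VEnCode", function(x) x@reClass)

#' @rdname accessors
#' @export
setGeneric("activityMatrix", function(x) standardGeneric("activityMatrix"))

#' @rdname accessors
#' @export
setMethod("activityMatrix", "BinaryLandscape", function(x) x@active)

#' @rdname accessors
#' @export
setGeneric("target", function(x) standardGeneric("target"))

#' @rdname accessors
#' @export
setMethod("target", "BinaryLandscape", function(x) x@target)

#' @rdname accessors
#' @export
setMethod("target", "VEnCode", function(x) x@target)

#' @rdname accessors
#' @export
setMethod("target", "SearchReport", function(x) x@target)

#' @rdname accessors
#' @export
setGeneric("vencodes", function(x) standardGeneric("vencodes"))

#' @rdname accessors
#' @export
setMethod("vencodes", "SearchReport", function(x) x@vencodes)

#' @rdname accessors
#' @export
setGeneric("eScore", function(x) standardGeneric("eScore"))

#' @rdname accessors
#' @export
setMethod("eScore", "QualityScore", function(x) x@e)

#' @rdname accessors
#' @export
setMethod("eScore", "VEnCode",
    function(x) if (is.null(x@quality)) NA_real_ else x@quality@e)

#' @rdname accessors
#' @export
setGeneric("zScoreValue", function(x) standardGeneric("zScoreValue"))

#' @rdname accessors
#' @export
setMethod("zScoreValue", "RobustnessScore", function(x) x@z)

setMethod("show", "RegulatoryProfiles", function(object) {
    cd <- colData(object)
    cat(sprintf(
        "RegulatoryProfiles: %d REs x %d samples (%d cell types)\n",
        nrow(object), ncol(object), length(unique(cd$cellType))))
    callNextMethod()
})

setMethod("show", "BinaryLandscape", function(object) {
    a <- object@active
    cat(sprintf(
        "BinaryLandscape for '%s': r = %d REs x c = %d cell types\n",
        object@target, nrow(a), ncol(a)))
    cat(sprintf("  mean non-target activity: %.3f\n",
        mean(a[, colnames(a) != object@target, drop = FALSE])))
})

setMethod("show", "VEnCode", function(object) {
    cat(sprintf("VEnCode (k = %d, %s) for '%s'\n", length(object@res),
                object@method, object@target))
    cat("  REs:", paste(object@res, collapse = ", "), "\n")
    if (!is.na(object@k1))
        cat(sprintf("  k1 = %d enhancers, k2 = %d promoters\n",
                    object@k1, object@k2))
    if (!is.null(object@quality) && !is.na(object@quality@e))
        cat(sprintf("  E = %.1f\n", object@quality@e))
})

setMethod("show", "SearchReport", function(object) {
    cat(sprintf(
        "SearchReport: %d VEnCode(s) for '%s' by %s (k = %d, %d iterations)\n",
        length(object@vencodes), object@target, object@method, object@k,
        object@nIterations))
})

setMethod("show", "QualityScore", function(object) {
    cat(sprintf("QualityScore: E_raw = %.3f", object@eRaw))
    if (!is.na(object@e))
        cat(sprintf(", E_best = %.3f, E = %.1f", object@eBest, object@e))
    cat(sprintf(" (n = %d sims)\n", object@nSims))
})

setMethod("show", "RobustnessScore", function(object) {
    cat(sprintf("RobustnessScore: z = %.1f%% (%d codes, %d train subset(s))\n",
                object@z, object@nCodesTested, length(object@donorsTrain)))
})

setMethod("show", "ExternalRESet", function(object) {
    cat(sprintf("ExternalRESet '%s' for '%s': %d intervals\n",
                object@source, object@cellType, length(object@intervals)))
})

setMethod("show", "PooledProfile", function(object) {
    cat(sprintf("PooledProfile '%s': %d cells pooled, %d REs ON\n",
                object@cellType, object@nCells, length(object@onREs)))
})
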