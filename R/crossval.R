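#' @include robustness.R
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges overlapsAny
#' @importFrom IRanges IRanges
NULL

# Canonical chromosome names: "chr1" and "1" refer to the same sequence.
# Genome-build mismatches are the caller's responsibility: no coordinate
# lifting is attempted here.
normalizeChrom <- function(chrom, aliasMap = NULL) {
    chrom <- as.character(chrom)
    if (!is.null(aliasMap)) {
        idx <- match(chrom, names(aliasMap))
        chrom[!is.na(idx)] <- aliasMap[idx[!is.na(idx)]]
    }
    sub("^chr", "", chrom)
}

#' Do two genomic intervals overlap?
#'
#' Intervals are 0-based half-open (BED convention).  Overlap is positional
#' only (strand ignored) and requires strictly more than 0 shared
#' nucleotides: overlap length = min(end) - max(start) > 0 on the same
#' chromosome.  "chr1" and "1" are treated as the same chromosome.
#'
#' @param a,b lists or data.frames with fields chrom, start, end
#'   (vectorized: recycled to common length).
#' @return logical vector.
#' @examples
#' intervalsOverlap(list(chrom = "chr1", start = 100, end = 200),
#'                  list(chrom = "chr1", start = 199, end = 300))  # TRUE
#' intervalsOverlap(list(chrom = "chr1", start = 100, end = 200),
#'                  list(chrom = "chr1", start = 200, end = 300))  # FALSE
#' @export
intervalsOverlap <- function(a, b) {
    chk <- function(x) {
        if (any(is.na(x$start) | is.na(x$end) | is.na(x$chrom)) ||
            any(x$end <= x$start) || any(x$start < 0))
            stop("malformed interval: need chrom, 0 <= start < end")
        x
    }
    a <- chk(as.list(a)); b <- chk(as.list(b))
    normalizeChrom(a$chrom) == normalizeChrom(b$chrom) &
        (pmin(a$end, b$end) - pmax(a$start, b$start)) > 0
}

# GRanges (1-based closed) from 0-based half-open coordinate columns; the
# two conventions map exactly, so the >0-nucleotide rule is plain GRanges
# overlap.
coordsToGRanges <- function(chrom, start, end) {
    GRanges(normalizeChrom(chrom), IRanges(start + 1, end))
}

# GRanges of a landscape's REs; errors naming REs without coordinates.
landscapeGRanges <- function(landscape, ids = reIds(landscape)) {
    iv <- landscape@intervals[match(ids, reIds(landscape)), , drop = FALSE]
    miss <- ids[is.na(iv$chrom) | is.na(iv$start) | is.na(iv$end)]
    if (length(miss))
        stop("RE(s) without genomic coordinates: ",
             paste(miss, collapse = ", "))
    gr <- coordsToGRanges(iv$chrom, iv$start, iv$end)
    names(gr) <- ids
    gr
}

#' Construct an external RE call set
#'
#' @param intervals a \linkS4class{GRanges}, or a data.frame with
#'   chrom/start/end columns in 0-based half-open coordinates.
#' @param source free-text assay/study tag.
#' @param cellType cell type the calls refer to.
#' @return an \linkS4class{ExternalRESet} (duplicates collapsed, strand
#'   dropped).
#' @export
ExternalRESet <- function(intervals, source = "external",
                          cellType = NA_character_) {
    if (is.data.frame(intervals)) {
        if (any(intervals$end <= intervals$start))
            stop("malformed interval(s): end must exceed start")
        intervals <- coordsToGRanges(intervals$chrom, intervals$start,
                                     intervals$end)
    }
    gr <- GRanges(normalizeChrom(seqnames(intervals)),
                  IRanges(BiocGenerics::start(intervals),
                          BiocGenerics::end(intervals)))
    new("ExternalRESet", source = source, cellType = cellType,
        intervals = unique(gr))
}

#' Read an external RE call set from a BED-style file
#'
#' Uses \pkg{rtracklayer} when available (BED/BroadPeak dialects), falling
#' back to a plain three-column BED read.
#'
#' @param path file path (BED3+ or BroadPeak).
#' @param source,cellType passed to [ExternalRESet()].
#' @return an \linkS4class{ExternalRESet}.
#' @export
readExternalRESet <- function(path, source = basename(path),
                              cellType = NA_character_) {
    gr <- if (requireNamespace("rtracklayer", quietly = TRUE))
        rtracklayer::import(path, format = "bed")
    else {
        bed <- utils::read.delim(path, header = FALSE,
                                 stringsAsFactors = FALSE)[, 1:3]
        coordsToGRanges(bed[[1L]], bed[[2L]], bed[[3L]])
    }
    ExternalRESet(gr, source = source, cellType = cellType)
}

setClass("ValidationReport",
    representation(code = "VEnCode", validatedK = "integer",
                   fraction = "numeric"))

setMethod("show", "ValidationReport", function(object) {
    cat(sprintf("ValidationReport: %d/%d REs validated (fraction %.2f)\n",
                object@validatedK, length(object@code@res),
                object@fraction))
})

#' Cross-validate a VEnCode against an external RE call set
#'
#' Counts how many of the code's REs overlap (by > 0 nucleotides) at least
#' one interval of the external set.
#'
#' @param code a \linkS4class{VEnCode}.
#' @param ext an \linkS4class{ExternalRESet}.
#' @param landscape the \linkS4class{BinaryLandscape} carrying the code's
#'   RE coordinates.
#' @return a \code{ValidationReport} with \code{validatedK} and
#'   \code{fraction} = validatedK / k.
#' @export
validateCode <- function(code, ext, landscape) {
    gr <- landscapeGRanges(landscape, code@res)
    # disjoint chromosome sets are a legitimate "no overlap", not a
    # user-facing warning
    hits <- suppressWarnings(overlapsAny(gr, ext@intervals))
    new("ValidationReport", code = code,
        validatedK = as.integer(sum(hits)),
        fraction = sum(hits) / length(hits))
}

#' Restrict a landscape to externally validated REs
#'
#' Keeps only REs with at least one overlapping interval in the external
#' set; searches run on the result yield pre-validated VEnCodes (validation
#' fraction 1 by construction).
#'
#' @param landscape a \linkS4class{BinaryLandscape} whose REs carry
#'   coordinates.
#' @param ext an \linkS4class{ExternalRESet}.
#' @return the restricted \linkS4class{BinaryLandscape}.
#' @export
restrictToValidated <- function(landscape, ext) {
    gr <- landscapeGRanges(landscape)
    keep <- suppressWarnings(overlapsAny(gr, ext@intervals))
    if (!any(keep))
        stop("no RE of the landscape overlaps the external set '",
             ext@source, "'")
    subsetREs(landscape, keep)
}

#' Match VEnCodes against a per-cell-type external call collection
#'
#' A code "matches" a cell type when every one of its REs overlaps at least
#' one active interval called for that cell type.  Returns the percentage
#' of codes matching each cell type, the raw material of the specificity
#' comparison against random k-subsets.
#'
#' @param codes list of \linkS4class{VEnCode}s (or a
#'   \linkS4class{SearchReport}).
#' @param collection named list of \linkS4class{ExternalRESet}s (or
#'   \linkS4class{GRanges}), one per cell type.
#' @param landscape the \linkS4class{BinaryLandscape} carrying RE
#'   coordinates.
#' @return named numeric vector of hit percentages per cell type.
#' @export
matchCodesAcrossDatabase <- function(codes, collection, landscape) {
    if (is(codes, "SearchReport")) codes <- vencodes(codes)
    stopifnot(length(codes) > 0, !is.null(names(collection)))
    hit <- vapply(collection, function(ext) {
        gr <- if (is(ext, "ExternalRESet")) ext@intervals else ext
        100 * mean(vapply(codes, function(cd) {
            all(suppressWarnings(
                overlapsAny(landscapeGRanges(landscape, cd@res), gr)))
        }, TRUE))
    }, 0)
    hit
}

#' Specificity index of per-cell-type hit percentages
#'
#' Target-cell hit percentage divided by the mean non-target hit
#' percentage.  When no non-target cell is ever hit the specificity is
#' infinite; \code{Inf} is returned as the documented sentinel for that
#' case rather than an arbitrary large number.
#'
#' @param codeHits named numeric vector of hit percentages (0-100) per cell
#'   type, e.g. from [matchCodesAcrossDatabase()].
#' @param targetCellType the target cell type (must be a name of
#'   \code{codeHits}).
#' @return the specificity index (>= 0, possibly \code{Inf}).
#' @export
specificityIndex <- function(codeHits, targetCellType) {
    if (!targetCellType %in% names(codeHits))
        stop("target '", targetCellType, "' missing from codeHits")
    if (any(codeHits < 0 | codeHits > 100))
        stop("hit fractions must be percentages in [0, 100]")
    tgt <- codeHits[[targetCellType]]
    nt <- mean(codeHits[setdiff(names(codeHits), targetCellType)])
    if (nt == 0) {
        if (tgt == 0) return(0)
        return(Inf)
    }
    tgt / nt
}
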