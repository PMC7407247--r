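#' @include utils.R
NULL

# Parse "chrN:start-end" style RE ids into 0-based half-open coordinates.
# Returns a data.frame(chrom, start, end) with NAs where the id does not
# embed coordinates.
parseEmbeddedCoords <- function(ids) {
    m <- regmatches(ids, regexec("^([^:]+):([0-9]+)-([0-9]+)$", ids))
    chrom <- vapply(m, function(x) if (length(x)) x[2] else NA_character_, "")
    start <- vapply(m, function(x) if (length(x)) as.numeric(x[3]) else
        NA_real_, 0)
    end <- vapply(m, function(x) if (length(x)) as.numeric(x[4]) else
        NA_real_, 0)
    bad <- !is.na(start) & end <= start
    if (any(bad))
        stop("malformed coordinates (end <= start) in RE id(s): ",
             paste(ids[bad], collapse = ", "))
    data.frame(chrom = chrom, start = start, end = end,
               stringsAsFactors = FALSE)
}

# Split FANTOM5-style sample labels into (cellType, donor).  The default
# dialect takes the LAST comma-separated token as the donor; everything
# before it is the cell-type name.  A custom `sampleRegex` with two capture
# groups (cell type, donor) overrides this.
parseSampleLabels <- function(labels, sampleRegex = NULL) {
    if (!is.null(sampleRegex)) {
        m <- regmatches(labels, regexec(sampleRegex, labels))
        ok <- lengths(m) >= 3L
        if (!all(ok))
            stop("sample label(s) not matching the supplied regex: ",
                 paste(labels[!ok], collapse = "; "))
        return(data.frame(
            cellType = trimws(vapply(m, `[`, "", 2L)),
            donor = trimws(vapply(m, `[`, "", 3L)),
            stringsAsFactors = FALSE))
    }
    parts <- strsplit(labels, ",")
    ok <- lengths(parts) >= 2L
    if (!all(ok))
        stop("unparseable sample header (expected 'cell type, donor'): ",
             paste(labels[!ok], collapse = "; "))
    data.frame(
        cellType = trimws(vapply(parts, function(p)
            paste(p[-length(p)], collapse = ","), "")),
        donor = trimws(vapply(parts, function(p) p[length(p)], "")),
        stringsAsFactors = FALSE)
}

#' Construct a RegulatoryProfiles object from a TPM matrix
#'
#' @param tpm numeric matrix of non-negative TPM values, RE ids as rownames.
#' @param cellType,donor character vectors, one entry per column of
#'   \code{tpm}.
#' @param reClass "promoter", "enhancer", or a per-RE vector; NA if unknown.
#' @param coords optional data.frame with chrom/start/end per RE (0-based
#'   half-open); when NULL, coordinates are parsed from RE ids of the form
#'   "chrN:start-end" where present.
#' @return a validated \linkS4class{RegulatoryProfiles}.
#' @export
RegulatoryProfiles <- function(tpm, cellType, donor,
                               reClass = NA_character_, coords = NULL) {
    tpm <- as.matrix(tpm)
    if (is.null(coords)) coords <- parseEmbeddedCoords(rownames(tpm))
    reClass <- rep_len(as.character(reClass), nrow(tpm))
    rd <- DataFrame(reClass = reClass, chrom = coords$chrom,
                    start = coords$start, end = coords$end,
                    row.names = rownames(tpm))
    cd <- DataFrame(cellType = as.character(cellType),
                    donor = as.character(donor),
                    row.names = sampleLabel(cellType, donor))
    colnames(tpm) <- rownames(cd)
    se <- SummarizedExperiment(assays = list(tpm = tpm), rowData = rd,
                               colData = cd)
    new("RegulatoryProfiles", se)
}

#' Read an RE-by-sample TPM table from a tab-separated file
#'
#' Expects a header row of "cell type, donor" sample names and RE ids in the
#' first column.  Ids of the form "chrN:start-end" have their genomic
#' interval (0-based half-open) attached automatically.
#'
#' @param path path to the TSV file.
#' @param reClass "promoter" or "enhancer" (applied to all rows), or NA.
#' @param sampleRegex optional regex with two capture groups (cell type,
#'   donor) for non-default header dialects.
#' @return a \linkS4class{RegulatoryProfiles}.
#' @export
readExpressionTable <- function(path, reClass = NA_character_,
                                sampleRegex = NULL) {
    if (!file.exists(path)) stop("input file not found: ", path)
    raw <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    ids <- as.character(raw[[1L]])
    if (anyDuplicated(ids))
        stop("duplicated RE id(s) in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    x <- as.matrix(raw[, -1L, drop = FALSE])
    if (!is.numeric(x)) {
        bad <- which(!vapply(raw[-1L], is.numeric, TRUE))
        stop("non-numeric TPM values in column(s): ",
             paste(colnames(raw)[-1L][bad], collapse = ", "))
    }
    if (any(!is.finite(x)) || any(x < 0)) {
        idx <- which(!is.finite(x) | x < 0, arr.ind = TRUE)[1L, ]
        stop(sprintf("negative or non-finite TPM at RE '%s', sample '%s'",
                     ids[idx[1L]], colnames(x)[idx[2L]]))
    }
    rownames(x) <- ids
    lab <- parseSampleLabels(colnames(x), sampleRegex)
    RegulatoryProfiles(x, lab$cellType, lab$donor, reClass = reClass)
}

#' Write a RegulatoryProfiles object back to the supported TSV dialect
#'
#' @param profiles a \linkS4class{RegulatoryProfiles}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTable <- function(profiles, path) {
    x <- tpm(profiles)
    cd <- colData(profiles)
    df <- data.frame(id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("id", sampleLabel(cd$cellType, cd$donor))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Build or read a curation specification
#'
#' A curation spec lists sample-name patterns to exclude and a map merging
#' cell-type categories (e.g. pooling "CD8+ T Cells (pluriselect)" into
#' "CD8+ T Cells").  Exclusion patterns are matched as fixed substrings
#' against the full "cell type, donor" sample label, so supplementary-style
#' exclusion lists can be supplied verbatim.
#'
#' @param excludeSamples character vector of patterns.
#' @param mergeMap named character vector: names are original cell-type
#'   names, values the merged category name.
#' @param path for \code{readCurationSpec}: a YAML file with keys
#'   \code{exclude_samples} and \code{merge_map}.
#' @return a list with elements \code{excludeSamples} and \code{mergeMap}.
#' @export
curationSpec <- function(excludeSamples = character(),
                         mergeMap = character()) {
    mergeMap <- unlist(mergeMap)
    if (length(mergeMap) && is.null(names(mergeMap)))
        stop("mergeMap must be named (original -> merged)")
    overlap <- intersect(names(mergeMap), excludeSamples)
    if (length(overlap))
        stop("merge sources also listed for exclusion: ",
             paste(overlap, collapse = ", "))
    list(excludeSamples = as.character(excludeSamples),
         mergeMap = mergeMap)
}

#' @rdname curationSpec
#' @export
readCurationSpec <- function(path) {
    y <- yaml::read_yaml(path)
    curationSpec(excludeSamples = unlist(y$exclude_samples),
                 mergeMap = unlist(y$merge_map))
}

#' Curate a profile set: drop excluded samples, merge cell-type categories
#'
#' Excluded patterns that match no sample are reported via message and
#' ignored.  Merging renames cell types so their donors pool under one
#' category; a merge that would collide two (cellType, donor) pairs is an
#' error suggesting donor re-suffixing.
#'
#' @param profiles a \linkS4class{RegulatoryProfiles}.
#' @param spec a curation spec from [curationSpec()]/[readCurationSpec()].
#' @return the curated \linkS4class{RegulatoryProfiles}.
#' @export
curateProfiles <- function(profiles, spec = curationSpec()) {
    cd <- colData(profiles)
    labels <- sampleLabel(cd$cellType, cd$donor)
    drop <- rep(FALSE, length(labels))
    for (pat in spec$excludeSamples) {
        hit <- grepl(pat, labels, fixed = TRUE)
        if (!any(hit))
            message("curation: exclusion pattern matched no sample: ", pat)
        drop <- drop | hit
    }
    keep <- !drop
    if (!any(keep)) stop("curation would exclude every sample")
    out <- profiles[, keep]
    cd <- colData(out)
    ct <- trimws(as.character(cd$cellType))
    mm <- spec$mergeMap
    if (length(mm)) {
        src <- trimws(names(mm))
        idx <- match(ct, src)
        ct[!is.na(idx)] <- trimws(mm[idx[!is.na(idx)]])
        key <- paste(ct, cd$donor, sep = "\r")
        if (anyDuplicated(key)) {
            dup <- ct[duplicated(key)][1L]
            stop("merging creates duplicate (cellType, donor) pairs in '",
                 dup, "'; re-suffix donors (e.g. 'donor1a', 'donor1b') ",
                 "before merging")
        }
    }
    colData(out)$cellType <- ct
    colnames(out) <- sampleLabel(ct, colData(out)$donor)
    validObject(out)
    out
}

#' Collapse non-target donors to per-cell-type mean TPM
#'
#' Averages the raw TPM of each non-target cell type's donors into a single
#' column (arithmetic mean of raw TPM, never of binarized values); target
#' donors are left uncollapsed and are not part of the returned matrix.
#'
#' @param profiles a \linkS4class{RegulatoryProfiles}.
#' @param target a cell type present in \code{profiles}.
#' @return numeric matrix, REs x non-target cell types, of donor-mean TPM.
#' @export
collapseNonTargetDonors <- function(profiles, target) {
    cts <- cellTypes(profiles)
    if (!target %in% cts)
        stop("target '", target, "' not found; available cell types: ",
             paste(cts, collapse = ", "))
    x <- tpm(profiles)
    ct <- as.character(colData(profiles)$cellType)
    nonTarget <- setdiff(cts, target)
    out <- vapply(nonTarget, function(g)
        rowMeans(x[, ct == g, drop = FALSE]), numeric(nrow(x)))
    out <- matrix(out, nrow = nrow(x),
                  dimnames = list(rownames(x), nonTarget))
    out
}

#' Add an external cell type (e.g. a cancer line) to a profile set
#'
#' Models an "in-silico patient": the extra cell type's donors/replicates
#' join the primary database and are subjected to the same exclusivity
#' criteria downstream.  RE universes are reconciled by intersection; the
#' number of REs dropped from each side is reported via message.
#'
#' @param profiles the primary \linkS4class{RegulatoryProfiles}.
#' @param extra a \linkS4class{RegulatoryProfiles} holding the cell type to
#'   add (one or more donors/replicates of a single new cell type, or
#'   several new cell types).
#' @return a combined \linkS4class{RegulatoryProfiles} restricted to the
#'   shared RE universe.
#' @export
addExternalCellType <- function(profiles, extra) {
    shared <- intersect(reIds(profiles), reIds(extra))
    if (!length(shared))
        stop("no shared REs between the primary table and the addition")
    clash <- intersect(cellTypes(profiles), cellTypes(extra))
    if (length(clash))
        stop("cell type(s) already present: ", paste(clash, collapse = ", "))
    dropped <- (nrow(profiles) - length(shared)) +
        (nrow(extra) - length(shared))
    if (dropped > 0)
        message("addExternalCellType: restricted to ", length(shared),
                " shared REs (", dropped, " dropped)")
    a <- profiles[shared, ]
    b <- extra[shared, ]
    cdA <- colData(a); cdB <- colData(b)
    x <- cbind(tpm(a), tpm(b))
    RegulatoryProfiles(x,
        cellType = c(as.character(cdA$cellType), as.character(cdB$cellType)),
        donor = c(as.character(cdA$donor), as.character(cdB$donor)),
        reClass = reClass(a),
        coords = as.data.frame(rowData(a)[, c("chrom", "start", "end")]))
}
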