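#' @include crossval.R
NULL

#' Pool per-cell RE "ON" calls into one binary profile
#'
#' Consolidates shallow single-cell activity calls by taking the union of
#' the per-cell "ON" RE sets (optionally requiring support from at least
#' \code{minCells} cells); every RE never called ON is OFF by definition.
#' Pooling is order-invariant and idempotent.
#'
#' @param perCellOnSets list of character vectors, one "ON" RE id set per
#'   cell; alternatively a cells x REs binary matrix with RE ids as column
#'   names.
#' @param cellType label for the pooled population.
#' @param minCells minimum number of cells an RE must be ON in to enter the
#'   pooled set (default 1, the plain union).
#' @return a \linkS4class{PooledProfile}.
#' @export
poolCells <- function(perCellOnSets, cellType, minCells = 1L) {
    if (is.matrix(perCellOnSets))
        perCellOnSets <- apply(perCellOnSets > 0, 1L, function(row)
            colnames(perCellOnSets)[row], simplify = FALSE)
    stopifnot(length(perCellOnSets) >= 1L)
    counts <- table(unlist(lapply(perCellOnSets, unique)))
    on <- sort(names(counts)[counts >= minCells])
    new("PooledProfile", cellType = cellType,
        nCells = length(perCellOnSets), onREs = as.character(on))
}

#' Inject a pooled single-cell profile into a bulk profile set
#'
#' The pooled profile becomes a new single-donor cell-type column: ON REs
#' get a sentinel TPM far above every activity threshold, OFF REs get 0, so
#' downstream binarization and search treat it exactly like a bulk cell
#' type.  Profile REs absent from the bulk RE universe are dropped with a
#' reported count.  Because the column has a single donor, the hold-out z
#' score is undefined for it.
#'
#' @param profiles the bulk \linkS4class{RegulatoryProfiles}.
#' @param profile a \linkS4class{PooledProfile}.
#' @param sentinelTPM TPM assigned to ON REs (default 10).
#' @param donor donor label for the new column (default "pooled").
#' @return the augmented \linkS4class{RegulatoryProfiles}.
#' @export
injectPooledProfile <- function(profiles, profile, sentinelTPM = 10,
                                donor = "pooled") {
    if (profile@cellType %in% cellTypes(profiles))
        stop("cell type '", profile@cellType, "' already present")
    ids <- reIds(profiles)
    dropped <- setdiff(profile@onREs, ids)
    if (length(dropped))
        message("injectPooledProfile: ", length(dropped),
                " ON RE(s) not in the bulk RE universe were dropped")
    newCol <- ifelse(ids %in% profile@onREs, sentinelTPM, 0)
    cd <- colData(profiles)
    x <- cbind(tpm(profiles), newCol)
    RegulatoryProfiles(x,
        cellType = c(as.character(cd$cellType), profile@cellType),
        donor = c(as.character(cd$donor), donor),
        reClass = reClass(profiles),
        coords = as.data.frame(
            rowData(profiles)[, c("chrom", "start", "end")]))
}

#' Remove a cell type from a profile set
#'
#' Inverse of [injectPooledProfile()]/[addExternalCellType()]: drops all
#' samples of one cell type.
#'
#' @param profiles a \linkS4class{RegulatoryProfiles}.
#' @param cellType the cell type to remove.
#' @return the reduced \linkS4class{RegulatoryProfiles}.
#' @export
removeCellType <- function(profiles, cellType) {
    keep <- colData(profiles)$cellType != cellType
    if (all(keep)) stop("cell type '", cellType, "' not found")
    out <- profiles[, keep]
    validObject(out)
    out
}

#' Read per-cell "ON" RE lists
#'
#' One file per cell with one RE id per line, or a single cells x REs
#' binary matrix TSV (cells in rows, RE ids in the header).
#'
#' @param paths character vector of per-cell list files, or a single matrix
#'   TSV path with \code{matrixFormat = TRUE}.
#' @param matrixFormat interpret \code{paths} as one binary matrix TSV.
#' @return list of character vectors of "ON" RE ids, one per cell.
#' @export
readPerCellOnSets <- function(paths, matrixFormat = FALSE) {
    if (matrixFormat) {
        m <- as.matrix(utils::read.delim(paths[1L], row.names = 1L,
                                         check.names = FALSE))
        return(apply(m > 0, 1L, function(row) colnames(m)[row],
                     simplify = FALSE))
    }
    lapply(paths, function(p) readLines(p, warn = FALSE))
}
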