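#' @include AllGenerics.R
NULL

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.null(seed) && !is.na(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

# Canonical unordered key for a set of RE ids (used for deduplication).
setKey <- function(ids) paste(sort(ids), collapse = "\r")

sampleLabel <- function(cellType, donor) paste(cellType, donor, sep = ", ")

#' Size of the combination space C(r, k)
#'
#' Number of distinct k-RE combinations available in an r-RE database,
#' choose(r, k).  Computed on the log scale so that atlas-scale inputs
#' (hundreds of thousands of REs) do not overflow.
#'
#' @param r number of REs in the database.
#' @param k number of REs per combination.
#' @return the number of combinations as a double (possibly very large).
#' @examples
#' combinationSpace(10, 3)       # 120
#' combinationSpace(201802, 4)   # ~6.9e19
#' @export
combinationSpace <- function(r, k) exp(lchoose(r, k))

#' Truth-table size of the exclusivity test
#'
#' The Boolean exclusivity condition over k REs and c cell types has a truth
#' table with 2^(c*k) rows.  Returned as a double; use \code{log10 = TRUE}
#' for sizes beyond double range.
#'
#' @param c number of cell types.
#' @param k number of REs per combination.
#' @param log10 return log10 of the row count instead.
#' @return 2^(c*k), or its log10.
#' @examples
#' truthTableRows(154, 4, log10 = TRUE)  # ~185.4
#' @export
truthTableRows <- function(c, k, log10 = FALSE) {
    lg <- c * k * log10(2)
    if (log10) lg else 10^lg
}

#' Donor-collapsing complexity reduction
#'
#' The average number of donors per cell type of a profile set: collapsing
#' non-target donors to a single per-cell-type data point shrinks the
#' database by this factor.
#'
#' @param profiles a \linkS4class{RegulatoryProfiles}.
#' @return mean donors per cell type (samples / cell types).
#' @export
donorComplexityReduction <- function(profiles) {
    stopifnot(is(profiles, "RegulatoryProfiles"))
    ncol(profiles) / length(cellTypes(profiles))
}

# Threshold comparison honouring the strict (">" vs ">=") setting.
exceeds <- function(x, threshold, strict = TRUE) {
    if (strict) x > threshold else x >= threshold
}
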