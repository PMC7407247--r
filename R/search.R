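#' @include binarize.R
NULL

newVEnCode <- function(landscape, ids, method, k1 = NA_integer_,
                       k2 = NA_integer_) {
    idx <- match(ids, reIds(landscape))
    new("VEnCode", target = landscape@target, res = ids,
        reClass = landscape@reClass[idx], method = method,
        k1 = as.integer(k1), k2 = as.integer(k2))
}

#' Test whether a set of REs is a VEnCode
#'
#' The exclusivity ("AND"-gate) criterion: all REs are active in the target
#' cell type and, for every other cell type, at least one RE of the set is
#' inactive.  Pure predicate with no side effects; equivalent to evaluating
#' the conjunctive-normal-form condition over the binary landscape.
#'
#' @param landscape a \linkS4class{BinaryLandscape}.
#' @param res character vector of RE ids (rows of \code{landscape}), or a
#'   \linkS4class{VEnCode}.
#' @return TRUE iff \code{res} is exclusive to the target.
#' @export
isVEnCode <- function(landscape, res) {
    if (is(res, "VEnCode")) res <- res@res
    a <- landscape@active
    miss <- setdiff(res, rownames(a))
    if (length(miss))
        stop("unknown RE id(s): ", paste(miss, collapse = ", "))
    sub <- a[res, , drop = FALSE]
    if (!all(sub[, landscape@target])) return(FALSE)
    nt <- colnames(a) != landscape@target
    all(colSums(!sub[, nt, drop = FALSE]) >= 1L)
}

#' Find VEnCodes by random sampling
#'
#' Draws uniform random k-subsets of the (filtered) target-active REs,
#' keeps those that satisfy the exclusivity criterion, and deduplicates
#' (codes are unordered RE sets).  When the requested budget covers the
#' whole combination space (\code{nSamples >= choose(r, k)}) the draw is
#' replaced by systematic enumeration, which dominates rejection sampling at
#' that budget and makes the hit set exhaustive.
#'
#' @param landscape a \linkS4class{BinaryLandscape}, normally already passed
#'   through [sparsityFilter()].
#' @param k code size.
#' @param nSamples number of draws (default 10000).
#' @param seed RNG seed; recorded in the report.
#' @param quota stop after this many distinct VEnCodes (default Inf).
#' @return a \linkS4class{SearchReport}.
#' @export
sampleVEnCodes <- function(landscape, k, nSamples = 10000, seed = NULL,
                           quota = Inf) {
    r <- nrow(landscape@active)
    if (r < k)
        stop("landscape has r = ", r, " REs, fewer than k = ", k)
    ids <- reIds(landscape)
    hits <- list()
    seen <- character()
    iter <- 0L
    if (choose(r, k) <= nSamples) {
        comb <- utils::combn(ids, k, simplify = FALSE)
        for (res in comb) {
            iter <- iter + 1L
            if (isVEnCode(landscape, res)) {
                hits[[length(hits) + 1L]] <-
                    newVEnCode(landscape, res, "sampling")
                if (length(hits) >= quota) break
            }
        }
    } else {
        withSeed(seed, for (i in seq_len(nSamples)) {
            iter <- iter + 1L
            res <- ids[sample.int(r, k)]
            key <- setKey(res)
            if (key %in% seen) next
            if (isVEnCode(landscape, res)) {
                seen <- c(seen, key)
                hits[[length(hits) + 1L]] <-
                    newVEnCode(landscape, res, "sampling")
                if (length(hits) >= quota) break
            }
        })
    }
    new("SearchReport", target = landscape@target, method = "sampling",
        k = as.integer(k), nIterations = iter, vencodes = hits,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Find VEnCodes by the greedy sparseness-ordered decision tree
#'
#' Greedy tree search over REs ordered by sparseness.  A first-level node is
#' opened for successive REs in global sparseness order; the cell types in
#' which the node's REs are all still active ("problematic" columns) drive
#' the next choice.  At each node the search first scans for single REs
#' inactive in every remaining problematic column (each such RE completes a
#' VEnCode; up to \code{neighbors} nearest by sparseness are taken, so one
#' node can yield several codes), then, failing that, opens up to
#' \code{nodesPerLevel} deeper nodes chosen as the sparsest REs counted over
#' the problematic columns only.  Node depth never exceeds k.  A partial
#' combination that is already exclusive with fewer than k REs is padded
#' with the next sparsest target-active REs up to k ("safety" padding);
#' supersets of an exclusive set are exclusive, so padding preserves
#' validity.
#'
#' @param landscape a \linkS4class{BinaryLandscape} (no sparsity filter
#'   needed: broadly active REs simply sort last).
#' @param k code size.
#' @param neighbors completions taken per node (default 3, the "nearest
#'   neighbors by order of sparseness").
#' @param nodesPerLevel nodes opened eagerly per level (default 3).
#' @param quota stop after this many distinct VEnCodes (default 20).
#' @param pad pad shorter exclusive combinations up to k (default TRUE).
#' @param backtrack continue with further sibling nodes, in sparseness
#'   order, while the quota is unmet (default TRUE).  Sparseness counts
#'   within the problematic columns are frequently tied, and a hard
#'   branching cap abandons recoverable landscapes when the useful sibling
#'   sits just past the cap; backtracking gives up only once a level is
#'   exhausted, at a cost bounded by \code{maxNodes}.
#' @param maxNodes global budget on decision-tree nodes (default 1e5).
#' @return a \linkS4class{SearchReport}; an empty report is a valid outcome
#'   (no VEnCode exists or none was found at this search effort).
#' @export
heuristicVEnCodes <- function(landscape, k, neighbors = 3L,
                              nodesPerLevel = 3L, quota = 20L, pad = TRUE,
                              backtrack = TRUE, maxNodes = 1e5) {
    stopifnot(k >= 1L)
    a <- landscape@active
    ntCols <- setdiff(colnames(a), landscape@target)
    globalOrder <- sortBySparseness(landscape)
    env <- new.env(parent = emptyenv())
    env$hits <- list()
    env$seen <- character()
    env$iter <- 0L

    emit <- function(ids) {
        if (pad && length(ids) < k) {
            extra <- setdiff(globalOrder, ids)
            ids <- c(ids, extra[seq_len(min(k - length(ids),
                                            length(extra)))])
        }
        key <- setKey(ids)
        if (key %in% env$seen) return(invisible())
        stopifnot(isVEnCode(landscape, ids))  # soundness guard
        env$seen <- c(env$seen, key)
        env$hits[[length(env$hits) + 1L]] <-
            newVEnCode(landscape, ids, "heuristic")
        invisible()
    }

    explore <- function(partial, problematic) {
        if (length(env$hits) >= quota) return(invisible())
        env$iter <- env$iter + 1L
        depth <- length(partial)
        if (!length(problematic)) {        # already exclusive
            emit(partial)
            return(invisible())
        }
        if (depth >= k) return(invisible())
        # completion scan: any RE inactive in all problematic columns
        inact <- rowSums(a[, problematic, drop = FALSE]) == 0L
        cand <- setdiff(rownames(a)[inact], partial)
        if (length(cand)) {
            cand <- globalOrder[globalOrder %in% cand]
            for (cc in cand[seq_len(min(neighbors, length(cand)))]) {
                emit(c(partial, cc))
                if (length(env$hits) >= quota) return(invisible())
            }
            return(invisible())
        }
        if (depth + 1L >= k) return(invisible())  # no room for a completer
        nodeOrder <- sortBySparseness(landscape, restrictTo = problematic)
        nodeOrder <- setdiff(nodeOrder, partial)
        opened <- 0L
        for (nd in nodeOrder) {
            if (!backtrack && opened >= nodesPerLevel) break
            stillActive <- problematic[a[nd, problematic]]
            if (length(stillActive) == length(problematic)) next  # no gain
            opened <- opened + 1L
            explore(c(partial, nd), stillActive)
            if (length(env$hits) >= quota || env$iter > maxNodes)
                return(invisible())
        }
        invisible()
    }

    for (root in globalOrder) {
        explore(root, ntCols[a[root, ntCols]])
        if (length(env$hits) >= quota || env$iter > maxNodes) break
    }
    new("SearchReport", target = landscape@target, method = "heuristic",
        k = as.integer(k), nIterations = env$iter, vencodes = env$hits)
}

#' Merge two binary landscapes over the same cell-type universe
#'
#' Stacks the RE rows of two landscapes (e.g. an enhancer and a promoter
#' landscape for the same target) into one, so mixed-class codes can be
#' tested and scored against a single activity matrix.
#'
#' @param x,y \linkS4class{BinaryLandscape}s sharing target and cell types.
#' @return a combined \linkS4class{BinaryLandscape}.
#' @export
mergeLandscapes <- function(x, y) {
    if (!identical(x@target, y@target))
        stop("landscapes have different targets")
    if (!setequal(cellTypes(x), cellTypes(y)))
        stop("landscapes have different cell-type universes")
    dup <- intersect(reIds(x), reIds(y))
    if (length(dup))
        stop("duplicate RE id(s) across landscapes: ",
             paste(dup, collapse = ", "))
    cols <- cellTypes(x)
    new("BinaryLandscape", target = x@target,
        active = rbind(x@active[, cols, drop = FALSE],
                       y@active[, cols, drop = FALSE]),
        reClass = c(x@reClass, y@reClass),
        intervals = rbind(x@intervals, y@intervals),
        thresholds = x@thresholds)
}

#' Find mixed enhancer + promoter VEnCodes (heuristic2)
#'
#' Takes the k1 sparsest target-active enhancers; if they are already
#' exclusive, they form the code.  Otherwise the "problematic" cell types in
#' which all k1 enhancers are co-active are identified and the greedy
#' heuristic searches the promoter landscape, restricted to those columns,
#' for k2 promoters that block them; the enhancer/promoter intersection is
#' then exclusive to the target.
#'
#' @param enhLandscape,promLandscape enhancer and promoter
#'   \linkS4class{BinaryLandscape}s sharing target and cell-type universe.
#' @param k1 number of enhancers.
#' @param k2 number of promoters (the promoter-stage code size).
#' @param quota,neighbors,nodesPerLevel passed to the promoter-stage
#'   [heuristicVEnCodes()].
#' @param padToFixed when the enhancers alone are exclusive, still append
#'   the k2 sparsest promoters so the total size is fixed (default FALSE:
#'   return the minimal code).
#' @return a \linkS4class{SearchReport} of mixed-class codes with k1/k2
#'   recorded per code.
#' @export
heuristic2VEnCodes <- function(enhLandscape, promLandscape, k1, k2,
                               quota = 20L, neighbors = 3L,
                               nodesPerLevel = 3L, padToFixed = FALSE) {
    if (!identical(enhLandscape@target, promLandscape@target))
        stop("landscapes have different targets")
    if (!setequal(cellTypes(enhLandscape), cellTypes(promLandscape)))
        stop("landscapes have different cell-type universes")
    merged <- mergeLandscapes(enhLandscape, promLandscape)
    enhOrder <- sortBySparseness(enhLandscape)
    if (length(enhOrder) < k1)
        stop("enhancer landscape has fewer than k1 = ", k1, " REs")
    sel <- enhOrder[seq_len(k1)]
    mk <- function(ids, nProm) {
        code <- newVEnCode(merged, ids, "heuristic2", k1 = k1, k2 = nProm)
        stopifnot(isVEnCode(merged, code))
        code
    }
    if (isVEnCode(enhLandscape, sel)) {
        ids <- sel
        nProm <- 0L
        if (padToFixed && k2 > 0L) {
            promPad <- sortBySparseness(promLandscape)
            promPad <- promPad[seq_len(min(k2, length(promPad)))]
            ids <- c(ids, promPad)
            nProm <- length(promPad)
        }
        return(new("SearchReport", target = merged@target,
                   method = "heuristic2", k = as.integer(k1 + nProm),
                   nIterations = 1L, vencodes = list(mk(ids, nProm))))
    }
    aE <- enhLandscape@active
    nt <- setdiff(cellTypes(enhLandscape), enhLandscape@target)
    problematic <- nt[colSums(!aE[sel, nt, drop = FALSE]) == 0L]
    promRestricted <- restrictCellTypes(promLandscape, problematic)
    promReport <- heuristicVEnCodes(promRestricted, k2,
                                    neighbors = neighbors,
                                    nodesPerLevel = nodesPerLevel,
                                    quota = quota)
    codes <- lapply(vencodes(promReport), function(pc)
        mk(c(sel, pc@res), length(pc@res)))
    new("SearchReport", target = merged@target, method = "heuristic2",
        k = as.integer(k1 + k2), nIterations = promReport@nIterations + 1L,
        vencodes = codes)
}

#' Rank VEnCodes by quality and keep the best n
#'
#' Scores every distinct code of one or more search reports with the
#' Monte-Carlo E score (see [eRaw()]) against a landscape containing all the
#' codes' REs, and returns the n highest-E codes.  Ties are broken by
#' smaller k, then by RE ids, so ranking is stable under report
#' concatenation order.
#'
#' @param reports a \linkS4class{SearchReport} or list of reports sharing a
#'   target.
#' @param n number of codes to return.
#' @param landscape the \linkS4class{BinaryLandscape} to score in (use
#'   [mergeLandscapes()] for mixed-class codes).
#' @param nSims Monte-Carlo simulations per code (default 2000).
#' @param seed RNG seed for the simulations.
#' @return list of up to n \linkS4class{VEnCode}s, best first, each with its
#'   \linkS4class{QualityScore} attached in the \code{quality} slot.
#' @export
topVEnCodes <- function(reports, n, landscape, nSims = 2000L, seed = NULL) {
    if (is(reports, "SearchReport")) reports <- list(reports)
    tgt <- unique(vapply(reports, function(r) r@target, ""))
    if (length(tgt) > 1L)
        stop("reports do not share a target: ", paste(tgt, collapse = ", "))
    codes <- unlist(lapply(reports, vencodes), recursive = FALSE)
    if (!length(codes)) return(list())
    keys <- vapply(codes, function(cd) setKey(cd@res), "")
    codes <- codes[!duplicated(keys)]
    c <- ncol(landscape@active)
    # one fixed seed for every code: scores, and hence the ranking, do not
    # depend on the order in which reports were concatenated
    scored <- lapply(codes, function(cd) {
        q <- eRaw(landscape, cd, nSims = nSims, seed = seed)
        q <- normalizeE(q, c = c, k = length(cd@res), seed = seed)
        cd@quality <- q
        cd
    })
    e <- vapply(scored, function(cd) cd@quality@e, 0)
    kk <- vapply(scored, function(cd) length(cd@res), 0L)
    idstr <- vapply(scored, function(cd) setKey(cd@res), "")
    ord <- order(-e, kk, idstr, method = "radix")
    scored[ord][seq_len(min(n, length(scored)))]
}

#' Write VEnCodes to a TSV score table
#'
#' One row per code: target, method, k, k1/k2, RE ids, classes,
#' coordinates (where known), and E-score fields when present.
#'
#' @param codes list of \linkS4class{VEnCode}s (or a
#'   \linkS4class{SearchReport}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVEnCodes <- function(codes, path) {
    if (is(codes, "SearchReport")) codes <- vencodes(codes)
    df <- do.call(rbind, lapply(codes, function(cd) {
        q <- cd@quality
        data.frame(target = cd@target, method = cd@method,
                   k = length(cd@res), k1 = cd@k1, k2 = cd@k2,
                   res = paste(cd@res, collapse = ";"),
                   reClass = paste(cd@reClass, collapse = ";"),
                   eRaw = if (is.null(q)) NA_real_ else q@eRaw,
                   eBest = if (is.null(q)) NA_real_ else q@eBest,
                   E = if (is.null(q)) NA_real_ else q@e,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(df))
        df <- data.frame(target = character(), method = character(),
                         k = integer(), k1 = integer(), k2 = integer(),
                         res = character(), reClass = character(),
                         eRaw = numeric(), eBest = numeric(), E = numeric())
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
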