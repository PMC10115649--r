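#' Validate a clone-tree parent map against the pigeonhole and crossing rules
#'
#' Checks that (i) the parent map is a tree rooted at the trunk (every
#' cluster reaches the trunk, no cycles); (ii) pigeonhole principle: in
#' every region each parent's PhyloCCF is at least the sum of its children's
#' PhyloCCFs minus the tolerance; (iii) crossing rule: a cluster may be an
#' ancestor of another only if its PhyloCCF is at least the descendant's
#' minus the tolerance in every region.
#'
#' @param parent named character vector mapping non-trunk clusters to their
#'   parent cluster
#' @param ccf cluster-by-region PhyloCCF matrix (rownames = cluster ids)
#' @param trunk trunk cluster id
#' @param tol absolute PhyloCCF tolerance (default 0.1)
#' @return TRUE if valid, FALSE otherwise
#' @export
validateCloneTree <- function(parent, ccf, trunk, tol = 0.1) {
    ids <- rownames(ccf)
    if (!setequal(names(parent), setdiff(ids, trunk))) return(FALSE)
    if (trunk %in% names(parent)) return(FALSE)
    if (!all(parent %in% ids)) return(FALSE)
    ## rootedness / acyclicity + ancestor lists
    anc <- list()
    for (v in names(parent)) {
        chain <- character(0)
        cur <- v
        repeat {
            if (cur == trunk) break
            pa <- parent[[cur]]
            if (pa %in% chain || pa == v) return(FALSE)
            chain <- c(chain, pa)
            if (length(chain) > length(ids)) return(FALSE)
            cur <- pa
        }
        anc[[v]] <- chain
    }
    ## crossing rule over all ancestor-descendant pairs
    for (v in names(anc))
        for (a in anc[[v]])
            if (any(ccf[a, ] < ccf[v, ] - tol)) return(FALSE)
    ## pigeonhole per parent per region
    for (pa in unique(parent)) {
        ch <- names(parent)[parent == pa]
        if (any(colSums(ccf[ch, , drop = FALSE]) > ccf[pa, ] + tol))
            return(FALSE)
    }
    TRUE
}

## DFS enumeration of all valid parent maps.  Clusters are assigned a parent
## in a fixed order; pairwise crossing, incremental cycle and incremental
## pigeonhole checks prune the search, and every complete map is confirmed
## with validateCloneTree (so the enumerator can never emit an invalid tree).
#' @noRd
.enumerateParentMaps <- function(ccf, trunk, tol = 0.1, cap = 1000L) {
    ids <- rownames(ccf)
    free <- setdiff(ids, trunk)
    if (!length(free)) return(list(maps = list(stats::setNames(character(0), character(0))),
                                   truncated = FALSE))
    ## deterministic order: decreasing total CCF, then id
    ord <- free[order(-rowSums(ccf[free, , drop = FALSE]), free)]
    ## pairwise crossing feasibility: can `a` be an ancestor of `b`?
    canAnc <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
    for (a in ids) for (b in ids) if (a != b)
        canAnc[a, b] <- all(ccf[a, ] >= ccf[b, ] - tol)
    maps <- list()
    truncated <- FALSE
    parent <- stats::setNames(rep(NA_character_, length(free)), ord)
    recurse <- function(k) {
        if (truncated) return()
        if (k > length(ord)) {
            pm <- parent
            if (validateCloneTree(pm, ccf, trunk, tol)) {
                if (length(maps) >= cap) { truncated <<- TRUE; return() }
                maps[[length(maps) + 1L]] <<- pm
            }
            return()
        }
        v <- ord[k]
        for (pa in ids[canAnc[, v]]) {
            if (pa == v) next
            ## incremental cycle check over currently assigned links
            cur <- pa; ok <- TRUE; steps <- 0L
            while (cur != trunk && !is.na(parent[cur])) {
                if (cur == v) { ok <- FALSE; break }
                if (!canAnc[cur, v]) { ok <- FALSE; break }  # ancestor-chain crossing
                cur <- parent[[cur]]
                steps <- steps + 1L
                if (steps > length(ids)) { ok <- FALSE; break }
            }
            if (cur == v) ok <- FALSE
            if (!ok) next
            parent[v] <<- pa
            ## incremental pigeonhole on the chosen parent
            ch <- names(parent)[!is.na(parent) & parent == pa]
            if (all(colSums(ccf[ch, , drop = FALSE]) <= ccf[pa, ] + tol))
                recurse(k + 1L)
            parent[v] <<- NA_character_
            if (truncated) return()
        }
    }
    recurse(1L)
    list(maps = maps, truncated = truncated)
}

#' Enumerate all valid clone trees
#'
#' Enumerates every parent map over the clusters that satisfies the
#' pigeonhole principle and the crossing rule, up to a cap.
#'
#' @param ccf cluster-by-region PhyloCCF matrix
#' @param trunk trunk cluster id; if NULL it is identified as the cluster
#'   whose PhyloCCF dominates all others (crossing-feasible ancestor of
#'   everything) with the largest total CCF
#' @param tol PhyloCCF tolerance
#' @param cap maximum number of trees to return
#' @return list with `maps` (list of parent maps), `trunk`, `truncated`
#' @export
enumerateTrees <- function(ccf, trunk = NULL, tol = 0.1, cap = 1000L) {
    if (is.null(trunk)) trunk <- .findTrunk(ccf, tol)
    res <- .enumerateParentMaps(ccf, trunk, tol, cap)
    if (res$truncated)
        warning("tree enumeration truncated at cap = ", cap)
    list(maps = res$maps, trunk = trunk, truncated = res$truncated)
}

#' @noRd
.findTrunk <- function(ccf, tol = 0.1) {
    ids <- rownames(ccf)
    dominating <- vapply(ids, function(a)
        all(vapply(setdiff(ids, a), function(b)
            all(ccf[a, ] >= ccf[b, ] - tol), TRUE)), TRUE)
    if (!any(dominating))
        stop("no trunk cluster: no cluster dominates all others in every region")
    cand <- ids[dominating]
    cand[order(-rowSums(ccf[cand, , drop = FALSE]), cand)][1]
}

#' Reconstruct the default clone tree
#'
#' Enumerates all valid trees and selects the default as the one maximizing
#' the summed parent-child PhyloCCF concordance (sum over edges of the
#' minimum over regions of parent minus child PhyloCCF), breaking ties
#' deterministically by lexicographic cluster order. If no valid tree
#' exists, spurious-cluster removal ([removeSpuriousClusters()]) is applied
#' and the reconstruction retried; if still none, an error with diagnostics
#' is raised.
#'
#' @param ccf cluster-by-region PhyloCCF matrix
#' @param clusterSizes named integer vector of mutations per cluster (used
#'   for parsimony during removal; defaults to 1 each)
#' @param segmentsOf optional named list: per cluster, the copy-number
#'   segment of each member mutation (for colocalization removal)
#' @param trunk optional trunk id
#' @param tol PhyloCCF tolerance
#' @param cap enumeration cap
#' @return a [CloneTree-class]; removed clusters (if any) are recorded in
#'   attribute "removed" of the object's `ccf` matrix rownames being absent
#' @examples
#' ccf <- rbind(trunk = c(1, 1), B = c(0.6, 0.1), C = c(0.1, 0.5))
#' buildCloneTree(ccf)
#' @export
buildCloneTree <- function(ccf, clusterSizes = NULL, segmentsOf = NULL,
                           trunk = NULL, tol = 0.1, cap = 1000L) {
    if (is.null(clusterSizes))
        clusterSizes <- stats::setNames(rep(1L, nrow(ccf)), rownames(ccf))
    rem <- removeSpuriousClusters(ccf, clusterSizes, segmentsOf, trunk, tol, cap)
    ccf <- rem$ccf
    if (is.null(trunk)) trunk <- .findTrunk(ccf, tol)
    res <- .enumerateParentMaps(ccf, trunk, tol, cap)
    if (!length(res$maps))
        stop("no valid clone tree even after spurious-cluster removal; ",
             "cluster CCFs: ", paste(utils::capture.output(print(round(ccf, 3))),
                                     collapse = " "))
    score <- vapply(res$maps, function(pm) {
        sum(vapply(names(pm), function(v)
            min(ccf[pm[[v]], ] - ccf[v, ]), 0))
    }, 0)
    keyOf <- vapply(res$maps, function(pm)
        paste(pm[order(names(pm))], collapse = "|"), "")
    best <- order(-score, keyOf)[1]
    tree <- new("CloneTree", ccf = ccf, parent = res$maps[[best]],
                trunk = trunk, alternatives = res$maps,
                truncated = res$truncated)
    attr(tree, "removed") <- rem$removed
    tree
}

#' Flag and remove spurious clusters
#'
#' Two-stage removal. First, clusters whose genomic locations indicate
#' copy-number-calling errors are flagged: more than 50% of members on a
#' single copy-number segment, for clusters of at least 5 mutations
#' (colocalization). Second, if no tree satisfying the pigeonhole and
#' crossing rules exists, the subset of clusters whose removal restores
#' feasibility while removing the smallest total number of mutations is
#' removed (exhaustive subset search up to 12 clusters, greedy
#' smallest-first beyond). The trunk cluster is never removed.
#'
#' @inheritParams buildCloneTree
#' @return list with `ccf` (retained clusters), `removed` (data.frame of
#'   cluster, reason)
#' @export
removeSpuriousClusters <- function(ccf, clusterSizes, segmentsOf = NULL,
                                   trunk = NULL, tol = 0.1, cap = 1000L) {
    removed <- data.frame(cluster = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
    if (is.null(trunk)) trunk <- .findTrunk(ccf, tol)
    ## stage 1: colocalization
    if (!is.null(segmentsOf)) {
        for (cl in setdiff(rownames(ccf), trunk)) {
            segs <- segmentsOf[[cl]]
            if (is.null(segs) || length(segs) < 5) next
            if (max(table(segs)) / length(segs) > 0.5) {
                removed <- rbind(removed, data.frame(
                    cluster = cl, reason = "colocalized"))
                ccf <- ccf[rownames(ccf) != cl, , drop = FALSE]
            }
        }
    }
    ## stage 2: tree feasibility under parsimony
    feasible <- function(m) length(.enumerateParentMaps(m, trunk, tol, 1L)$maps) > 0
    if (!feasible(ccf)) {
        cand <- setdiff(rownames(ccf), trunk)
        found <- NULL
        if (length(cand) <= 12L) {
            subsets <- .allSubsets(cand)
            cost <- vapply(subsets, function(s) sum(clusterSizes[s]), 0)
            key <- vapply(subsets, function(s) paste(sort(s), collapse = "|"), "")
            for (i in order(cost, lengths(subsets), key)) {
                s <- subsets[[i]]
                if (!length(s)) next
                m <- ccf[!rownames(ccf) %in% s, , drop = FALSE]
                if (feasible(m)) { found <- s; break }
            }
        } else {
            left <- ccf
            found <- character(0)
            while (!feasible(left) && nrow(left) > 1) {
                cc <- setdiff(rownames(left), trunk)
                drop <- cc[order(clusterSizes[cc], cc)][1]
                found <- c(found, drop)
                left <- left[rownames(left) != drop, , drop = FALSE]
            }
        }
        if (is.null(found))
            stop("invalid-state: no removal subset restores tree feasibility")
        removed <- rbind(removed, data.frame(
            cluster = found, reason = "tree-infeasible"))
        ccf <- ccf[!rownames(ccf) %in% found, , drop = FALSE]
    }
    list(ccf = ccf, removed = removed)
}

#' @noRd
.allSubsets <- function(x) {
    out <- list(character(0))
    for (el in x) out <- c(out, lapply(out, function(s) c(s, el)))
    out
}
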