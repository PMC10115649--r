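#' Pre-cluster mutations by presence/absence pattern
#'
#' Each mutation is called present in a region when at least one mutant read
#' is observed there; mutations are partitioned into groups by their exact
#' presence pattern across regions. Groups with fewer than five mutations
#' are retained but flagged not clusterable (their members are later
#' assigned to the nearest existing cluster).
#'
#' @param varCounts mutation-by-region matrix of variant read counts
#' @return data.frame with mutation (rowname id), pattern (string of 0/1),
#'   clusterable (logical)
#' @examples
#' m <- rbind(a = c(3, 0), b = c(5, 9))
#' preclusterByPresence(m)
#' @export
preclusterByPresence <- function(varCounts) {
    stopifnot(ncol(varCounts) >= 2)
    pat <- apply(varCounts >= 1, 1, function(r) paste(as.integer(r), collapse = ""))
    sizes <- table(pat)
    data.frame(
        mutation = rownames(varCounts),
        pattern = unname(pat),
        clusterable = unname(sizes[pat] >= 5),
        stringsAsFactors = FALSE)
}

#' Cluster-count cap for a presence group
#'
#' Groups with at least 50 mutations are capped at 10 clusters; smaller
#' groups at floor(n / 5) (so a 23-mutation group allows at most 4
#' clusters), preventing over-clustering of small groups.
#'
#' @param n number of mutations in the group
#' @return integer cap (may be 0 for n < 5)
#' @export
clusterCountCap <- function(n) {
    if (n >= 50) 10L else as.integer(floor(n / 5))
}

#' Cluster one presence group on its PhyloCCF vectors
#'
#' Multi-region Gaussian-mixture clustering (mclust) on the per-mutation
#' PhyloCCF vectors with model selection by BIC, with the number of
#' components capped by [clusterCountCap()]. This replaces a
#' Dirichlet-process sampler with a deterministic model-based clustering;
#' the presence pre-grouping and the cluster-count caps are applied exactly.
#'
#' @param ccf mutation-by-region numeric matrix of PhyloCCFs (one group)
#' @param cap maximum number of clusters; defaults to the cap rule
#' @return integer vector of cluster assignments (1-based, one per row)
#' @export
clusterGroup <- function(ccf, cap = clusterCountCap(nrow(ccf))) {
    n <- nrow(ccf)
    if (cap < 1L || n < 2L) return(rep(1L, n))
    if (all(apply(ccf, 2, function(cc) max(cc) - min(cc) < 1e-9)))
        return(rep(1L, n))
    G <- seq_len(min(cap, n))
    fit <- tryCatch(suppressWarnings({
        bic <- mclust::mclustBIC(ccf, G = G,
                                 modelNames = c("EII", "VII", "EEI", "VVI"),
                                 verbose = FALSE)
        mclust::summaryMclustBIC(bic, ccf)
    }), error = function(e) NULL)
    if (is.null(fit) || !length(fit$classification)) return(rep(1L, n))
    as.integer(fit$classification)
}

#' Cluster all mutations of a tumour
#'
#' Full clustering pipeline: presence/absence pre-grouping, per-group
#' Gaussian-mixture clustering under the cluster-count caps, within-group
#' merging of mixture components with near-identical mean PhyloCCF vectors
#' (such components are over-splits of heavy-tailed CCF noise and carry no
#' clonal information), and post hoc assignment of small (< 5 mutation)
#' groups to the nearest existing cluster by Euclidean distance between
#' PhyloCCF vectors.
#'
#' @param ccfMatrix mutation-by-region PhyloCCF matrix (rownames = mutation
#'   ids)
#' @param varCounts mutation-by-region variant-read-count matrix (same rows)
#' @param mergeTol merge mixture components closer than this in L-infinity
#'   distance between mean PhyloCCF vectors. The default 0.15 sits above the
#'   per-arm CCF bias introduced by integer copy-number reporting (about
#'   0.5 / CN, i.e. 15-25% at CCF 1, the scale of the spurious side modes
#'   that bias produces) and below the smallest clone separation the
#'   clustering aims to resolve (0.2)
#' @return data.frame with mutation, cluster (character id), pattern,
#'   from_small_group
#' @export
clusterMutations <- function(ccfMatrix, varCounts, mergeTol = 0.15) {
    stopifnot(identical(rownames(ccfMatrix), rownames(varCounts)))
    pre <- preclusterByPresence(varCounts)
    assign <- rep(NA_character_, nrow(ccfMatrix))
    names(assign) <- rownames(ccfMatrix)
    cid <- 0L
    for (pat in unique(pre$pattern[pre$clusterable])) {
        idx <- which(pre$pattern == pat)
        cl <- clusterGroup(ccfMatrix[idx, , drop = FALSE])
        cl <- .mergeCloseClusters(ccfMatrix[idx, , drop = FALSE], cl, mergeTol)
        for (g in sort(unique(cl))) {
            cid <- cid + 1L
            assign[idx[cl == g]] <- sprintf("C%d", cid)
        }
    }
    if (!any(!is.na(assign)))
        stop("no clusterable presence group (need one group with >= 5 mutations)")
    ## centroids of existing clusters
    cls <- sort(unique(assign[!is.na(assign)]))
    cent <- t(vapply(cls, function(cc)
        colMeans(ccfMatrix[assign %in% cc, , drop = FALSE]),
        numeric(ncol(ccfMatrix))))
    small <- which(is.na(assign))
    for (i in small) {
        d <- rowSums(sweep(cent, 2, ccfMatrix[i, ])^2)
        assign[i] <- cls[which.min(d)]
    }
    data.frame(
        mutation = rownames(ccfMatrix),
        cluster = unname(assign),
        pattern = pre$pattern,
        from_small_group = !pre$clusterable,
        stringsAsFactors = FALSE)
}

## Iteratively merge the closest pair of clusters while their mean PhyloCCF
## vectors are within `tol` in L-infinity distance.
#' @noRd
.mergeCloseClusters <- function(ccf, cl, tol) {
    if (tol <= 0) return(cl)
    repeat {
        ids <- sort(unique(cl))
        if (length(ids) < 2L) return(cl)
        cent <- t(vapply(ids, function(g)
            colMeans(ccf[cl == g, , drop = FALSE]), numeric(ncol(ccf))))
        d <- as.matrix(stats::dist(cent, method = "maximum"))
        diag(d) <- Inf
        if (min(d) >= tol) return(cl)
        p <- which(d == min(d), arr.ind = TRUE)[1, ]
        cl[cl == ids[max(p)]] <- ids[min(p)]
    }
}
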