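#' Count whole-genome doublings in one region from segment copy numbers
#'
#' If the major allele has copy number >= 2 across at least 50% of the
#' genome (length-weighted) the region is taken to have undergone one WGD;
#' if the major allele has copy number >= 3 across at least 50% it has
#' undergone two. "At least 50%" is inclusive (>= 0.5).
#'
#' @param majorCN per-segment major allele copy numbers
#' @param lengths per-segment lengths (bp); equal weights when omitted
#' @return integer 0, 1 or 2 (NA for an empty segmentation)
#' @examples
#' countWGDPerRegion(c(2, 2, 1), c(60, 10, 30))   # 1
#' countWGDPerRegion(c(3, 3, 1), c(40, 15, 45))   # 2
#' @export
countWGDPerRegion <- function(majorCN, lengths = NULL) {
    if (!length(majorCN)) return(NA_integer_)
    if (is.null(lengths)) lengths <- rep(1, length(majorCN))
    stopifnot(length(lengths) == length(majorCN), all(lengths >= 0))
    tot <- sum(lengths)
    if (tot <= 0) return(NA_integer_)
    if (sum(lengths[majorCN >= 3]) / tot >= 0.5) return(2L)
    if (sum(lengths[majorCN >= 2]) / tot >= 0.5) return(1L)
    0L
}

#' Fraction of doubled mutations in a cluster within one region
#'
#' A mutation is doubled when its mutation copy number exceeds 1.5. Only
#' mutations lying in genomic segments whose major copy number equals the
#' value expected from the region's WGD count alone (2^nWGD: 1 with no WGD,
#' 2 after one, 4 after two) are eligible -- segments above that value are
#' contaminated by amplification events and segments below by post-WGD
#' losses, both of which distort the doubled fraction.
#'
#' @param mutCN mutation copy numbers of the cluster's members in the region
#' @param majorCN major copy number of the segment each member lies in
#' @param nWGD the region's WGD count (0, 1 or 2)
#' @return fraction in \[0, 1\], or NA when no member is eligible
#' @examples
#' doubledFraction(c(2.1, 1.9, 0.9, 1.1), c(2, 2, 2, 2), 1)  # 0.5
#' @export
doubledFraction <- function(mutCN, majorCN, nWGD) {
    stopifnot(length(mutCN) == length(majorCN))
    eligible <- !is.na(mutCN) & !is.na(majorCN) & majorCN == 2^nWGD
    if (!any(eligible)) return(NA_real_)
    mean(mutCN[eligible] > 1.5)
}

#' Flag genome-doubled clusters from doubled fractions
#'
#' A cluster is called genome-doubled when its doubled fraction reaches 0.25
#' in at least one region; once called, a lower threshold of 0.1 extends the
#' cluster's doubled-region set to other regions (compensating for
#' region-to-region differences in detection power). Both thresholds are
#' inclusive.
#'
#' @param fractions cluster-by-region matrix of doubled fractions (NA where
#'   not computable)
#' @param primary,secondary the two thresholds
#' @return data.frame with cluster, doubled (logical), regions
#'   (comma-separated region ids where the cluster is doubled)
#' @export
flagGDClusters <- function(fractions, primary = 0.25, secondary = 0.1) {
    stopifnot(is.matrix(fractions))
    regions <- colnames(fractions)
    out <- lapply(rownames(fractions), function(cl) {
        fr <- fractions[cl, ]
        prim <- !is.na(fr) & fr >= primary
        if (!any(prim))
            return(data.frame(cluster = cl, doubled = FALSE, regions = "",
                              stringsAsFactors = FALSE))
        ext <- !is.na(fr) & fr >= secondary
        data.frame(cluster = cl, doubled = TRUE,
                   regions = paste(regions[ext], collapse = ","),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Infer distinct WGD events from genome-doubled clusters
#'
#' Doubled subclonal clusters sharing an identical doubled-region set are
#' merged into a single WGD event (they may have been doubled by the same
#' event); clusters doubled in different, even if overlapping, region sets
#' must reflect distinct (parallel) WGD events. A doubled truncal cluster
#' yields a truncal event. Events are assigned to regions respecting the
#' per-region WGD counts supplied as input: doubled subclonal clusters are
#' processed deepest-first (lowest mean PhyloCCF first) and the truncal
#' cluster last, because a subclonal WGD sweep also doubles every ancestral
#' cluster in the swept regions, so the deepest doubled cluster explains the
#' doubling of its ancestors there; regions whose capacity is exhausted are
#' dropped from later events. When no doubled cluster exists, WGD events
#' implied by the per-region counts are assigned by maximum parsimony:
#' regions harbouring WGDs are presumed to share an event where possible
#' (one event per count level, covering every region reaching that level).
#' At most two subclonal events are reported; beyond that, the two events
#' with the largest region-set overlap are merged iteratively and the
#' result is flagged for review.
#'
#' @param flags output of [flagGDClusters()]
#' @param regionCounts named integer vector of per-region WGD counts
#' @param clusterMeta data.frame with cluster, is_trunk (logical), mean_ccf
#'   (mean PhyloCCF across regions, used for the deepest-first ordering)
#' @return a [WGDEventSet-class]
#' @export
inferWGDEvents <- function(flags, regionCounts, clusterMeta) {
    regions <- names(regionCounts)
    stopifnot(!is.null(regions))
    flagged <- flags[flags$doubled, , drop = FALSE]
    bad <- setdiff(unlist(strsplit(flagged$regions, ",")), regions)
    if (length(bad))
        stop("invalid-argument: flags reference unknown region(s) ",
             paste(bad, collapse = ","))
    meta <- clusterMeta[match(flagged$cluster, clusterMeta$cluster), ]
    capacity <- regionCounts
    events <- list()
    reviewFlag <- FALSE

    takeRegions <- function(rs) {
        ok <- rs[capacity[rs] > 0]
        capacity[ok] <<- capacity[ok] - 1L
        ok
    }

    ## subclonal doubled clusters: merge identical region sets, deepest first
    subFlag <- flagged[!meta$is_trunk, , drop = FALSE]
    subMeta <- meta[!meta$is_trunk, , drop = FALSE]
    if (nrow(subFlag)) {
        sets <- split(seq_len(nrow(subFlag)), subFlag$regions)
        depth <- vapply(sets, function(i) min(subMeta$mean_ccf[i]), 0)
        for (si in order(depth)) {
            idx <- sets[[si]]
            rs <- strsplit(subFlag$regions[idx[1]], ",")[[1]]
            got <- takeRegions(rs)
            if (!length(got)) next
            events[[length(events) + 1L]] <- list(
                clonality = "subclonal", regions = got,
                source = "doubled-cluster",
                clusters = paste(sort(subFlag$cluster[idx]), collapse = ","))
        }
    }
    ## truncal doubled cluster(s)
    truFlag <- flagged[meta$is_trunk, , drop = FALSE]
    for (i in seq_len(nrow(truFlag))) {
        rs <- strsplit(truFlag$regions[i], ",")[[1]]
        got <- takeRegions(rs)
        if (!length(got)) next
        events[[length(events) + 1L]] <- list(
            clonality = if (setequal(got, regions)) "truncal" else "subclonal",
            regions = got, source = "doubled-cluster",
            clusters = truFlag$cluster[i])
    }
    ## parsimony fallback when no doubled cluster was identified
    if (!nrow(flagged) && any(regionCounts > 0)) {
        for (lev in seq_len(max(regionCounts))) {
            rs <- regions[regionCounts >= lev]
            events[[length(events) + 1L]] <- list(
                clonality = if (setequal(rs, regions)) "truncal" else "subclonal",
                regions = rs, source = "parsimony", clusters = NA_character_)
        }
    }
    ## cap subclonal events at 2 by merging the largest-overlap pair
    isSub <- function(ev) vapply(ev, function(e) e$clonality == "subclonal", TRUE)
    if (sum(isSub(events)) > 2L) reviewFlag <- TRUE
    while (sum(isSub(events)) > 2L) {
        si <- which(isSub(events))
        pairs <- utils::combn(si, 2)
        ov <- apply(pairs, 2, function(p)
            length(intersect(events[[p[1]]]$regions, events[[p[2]]]$regions)))
        p <- pairs[, which.max(ov)]
        merged <- list(
            clonality = "subclonal",
            regions = union(events[[p[1]]]$regions, events[[p[2]]]$regions),
            source = "doubled-cluster",
            clusters = paste(stats::na.omit(c(events[[p[1]]]$clusters,
                                              events[[p[2]]]$clusters)),
                             collapse = ","))
        events[[p[1]]] <- merged
        events <- events[-p[2]]
    }
    ev <- if (length(events)) data.frame(
        event_id = paste0("GD", seq_along(events)),
        clonality = vapply(events, `[[`, "", "clonality"),
        regions = vapply(events, function(e)
            paste(sort(e$regions), collapse = ","), ""),
        source = vapply(events, `[[`, "", "source"),
        clusters = vapply(events, `[[`, "", "clusters"),
        stringsAsFactors = FALSE
    ) else data.frame(event_id = character(0), clonality = character(0),
                      regions = character(0), source = character(0),
                      clusters = character(0), stringsAsFactors = FALSE)
    new("WGDEventSet", events = ev, regionCounts = regionCounts,
        status = tumourWGDStatus(ev), reviewFlag = reviewFlag)
}

#' Tumour-level WGD status
#'
#' @param events event data.frame (as in [WGDEventSet-class]) or a
#'   [WGDEventSet-class]
#' @return "no_wgd", "truncal_only" or "subclonal"
#' @export
tumourWGDStatus <- function(events) {
    if (is(events, "WGDEventSet")) events <- wgdEvents(events)
    if (!nrow(events)) return("no_wgd")
    if (any(events$clonality == "subclonal")) return("subclonal")
    "truncal_only"
}

#' Run the full subclonal/parallel WGD detector on one tumour
#'
#' Computes per-cluster, per-region doubled fractions from mutation copy
#' numbers (restricted to segments at the expected major copy number given
#' each region's WGD count), flags genome-doubled clusters with the 0.25 /
#' 0.1 thresholds, and infers merged, capacity-respecting WGD events.
#'
#' @param mutTable data.frame with mutation, sample_id, cluster, mut_cn,
#'   major_cn (one row per mutation per region)
#' @param regionCounts named integer vector of per-region WGD counts (e.g.
#'   from [countWGDPerRegion()])
#' @param trunkCluster id of the truncal cluster
#' @return a [WGDEventSet-class]
#' @export
detectWGD <- function(mutTable, regionCounts, trunkCluster) {
    regions <- names(regionCounts)
    clusters <- sort(unique(mutTable$cluster))
    fr <- matrix(NA_real_, length(clusters), length(regions),
                 dimnames = list(clusters, regions))
    mccf <- numeric(length(clusters))
    for (ci in seq_along(clusters)) {
        rows <- mutTable[mutTable$cluster == clusters[ci], , drop = FALSE]
        for (r in regions) {
            rr <- rows[rows$sample_id == r, , drop = FALSE]
            if (nrow(rr))
                fr[ci, r] <- doubledFraction(rr$mut_cn, rr$major_cn,
                                             regionCounts[[r]])
        }
        mccf[ci] <- mean(pmin(rows$mut_cn, 2), na.rm = TRUE)
    }
    meta <- data.frame(cluster = clusters,
                       is_trunk = clusters == trunkCluster,
                       mean_ccf = mccf, stringsAsFactors = FALSE)
    inferWGDEvents(flagGDClusters(fr), regionCounts, meta)
}
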