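#' Assign evolutionary events to the edges of a clone phylogeny
#'
#' SNVs are split between the trunk and the subclonal edges so that the
#' truncal proportion is preserved: the trunk receives
#' `round(nSnvs * truncalFraction)` SNVs and the remainder are distributed
#' uniformly at random over subclonal edges. Under the infinite-sites
#' assumption each SNV locus is used exactly once in the whole tree. Copy
#' number gains and losses are drawn per edge (Poisson counts), hit a
#' uniformly chosen chromosome arm and are assigned to a random allele.
#' Whole-genome-doubling events are placed on the edges named in
#' `wgdChildren`. Within each edge all events are applied in a uniformly
#' random order, so SNVs can occur both before and after SCNAs and WGDs.
#'
#' @param phylo a [ClonePhylogeny-class]
#' @param nSnvs total number of somatic SNVs
#' @param truncalFraction fraction of SNVs on the trunk, in \[0, 1\]
#' @param nArms number of chromosome-arm segments loci are grouped into
#' @param scnaTrunkRate,scnaEdgeRate Poisson means for the number of SCNA
#'   events on the trunk and on each subclonal edge
#' @param gainProb probability that an SCNA is a gain (vs a single-copy loss)
#' @param wgdChildren integer vector of child-node ids whose incoming edge
#'   carries a WGD event (use the MRCA id for a truncal WGD)
#' @return data.frame with columns kind, parent, child, locus, arm, allele,
#'   magnitude, order_index; `order_index` is the within-edge application
#'   order
#' @examples
#' set.seed(1)
#' ph <- simulateTopology(4)
#' ev <- assignEvents(ph, nSnvs = 100, truncalFraction = 0.6)
#' table(ev$kind)
#' @export
assignEvents <- function(phylo, nSnvs, truncalFraction, nArms = 44L,
                         scnaTrunkRate = 3, scnaEdgeRate = 0.6,
                         gainProb = 0.5, wgdChildren = integer(0)) {
    stopifnot(is(phylo, "ClonePhylogeny"), nSnvs >= 0)
    if (!is.numeric(truncalFraction) || truncalFraction < 0 || truncalFraction > 1)
        stop("'truncalFraction' must lie in [0, 1]")
    p <- cloneParents(phylo)
    trunkChild <- phylo@mrca
    subChildren <- subclonalEdgeChildren(phylo)
    nTrunk <- round(nSnvs * truncalFraction)
    nSub <- nSnvs - nTrunk
    if (nSub > 0 && length(subChildren) == 0L)
        stop("subclonal SNVs requested but the tree has no subclonal edges")
    loci <- seq_len(nSnvs)
    locusArm <- if (nSnvs) sample.int(nArms, nSnvs, replace = TRUE) else integer(0)
    snvChild <- c(rep(trunkChild, nTrunk),
                  if (nSub) sample(subChildren, nSub, replace = TRUE) else integer(0))
    ev <- data.frame(
        kind = rep("SNV", nSnvs),
        child = as.integer(snvChild),
        locus = loci,
        arm = locusArm,
        allele = rep("A", nSnvs),
        magnitude = rep(NA_integer_, nSnvs),
        stringsAsFactors = FALSE
    )
    ## SCNAs per edge
    for (ch in as.integer(names(p))) {
        rate <- if (ch == trunkChild) scnaTrunkRate else scnaEdgeRate
        k <- stats::rpois(1L, rate)
        if (k > 0L) {
            isGain <- stats::runif(k) < gainProb
            ev <- rbind(ev, data.frame(
                kind = ifelse(isGain, "GAIN", "LOSS"),
                child = ch,
                locus = NA_integer_,
                arm = sample.int(nArms, k, replace = TRUE),
                allele = sample(c("A", "B"), k, replace = TRUE),
                magnitude = ifelse(isGain, 1L, NA_integer_),
                stringsAsFactors = FALSE
            ))
        }
    }
    if (length(wgdChildren)) {
        bad <- setdiff(as.integer(wgdChildren), as.integer(names(p)))
        if (length(bad)) stop("wgdChildren must name existing edges (child ids)")
        ev <- rbind(ev, data.frame(
            kind = "WGD", child = as.integer(wgdChildren),
            locus = NA_integer_, arm = NA_integer_, allele = NA_character_,
            magnitude = NA_integer_, stringsAsFactors = FALSE
        ))
    }
    ev$parent <- unname(p[as.character(ev$child)])
    ## uniformly random within-edge application order
    ev$order_index <- NA_integer_
    for (ch in unique(ev$child)) {
        idx <- which(ev$child == ch)
        ev$order_index[idx] <- sample.int(length(idx))
    }
    ev <- ev[order(ev$child, ev$order_index), , drop = FALSE]
    rownames(ev) <- NULL
    ev[, c("kind", "parent", "child", "locus", "arm", "allele",
           "magnitude", "order_index")]
}
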