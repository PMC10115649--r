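#' Mutational intratumour heterogeneity
#'
#' Fraction of classified mutations that are subclonal: subclonal /
#' (truncal + subclonal). Mutations removed during tree building are
#' excluded from both counts.
#'
#' @param statuses character vector of tumour-level mutation statuses
#'   ("truncal"/"subclonal"; other values are ignored)
#' @return fraction in \[0, 1\] (NA when nothing is classified)
#' @examples
#' mutationalITH(c(rep("truncal", 60), rep("subclonal", 40)))  # 0.4
#' @export
mutationalITH <- function(statuses) {
    n <- sum(statuses %in% c("truncal", "subclonal"))
    if (!n) return(NA_real_)
    sum(statuses == "subclonal") / n
}

#' Copy-number state of segments relative to sample ploidy
#'
#' Integer copy numbers are compared with the sample ploidy using the
#' standard log-ratio thresholds mapped to the copy-number scale: loss when
#' CN / ploidy < 1.5 / 2, gain when CN / ploidy > 2.5 / 2 and amplification
#' when CN > 2 * ploidy; anything else is neutral.
#'
#' @param totalCN per-segment total copy numbers
#' @param ploidy sample ploidy
#' @return character vector in {"loss", "neutral", "gain", "amp"}
#' @export
segmentStates <- function(totalCN, ploidy) {
    st <- rep("neutral", length(totalCN))
    st[totalCN / ploidy < 1.5 / 2] <- "loss"
    st[totalCN / ploidy > 2.5 / 2] <- "gain"
    st[totalCN > 2 * ploidy] <- "amp"
    st
}

#' SCNA intratumour heterogeneity
#'
#' Length-weighted fraction of the SCNA-involved genome whose events are
#' heterogeneous, i.e. not present identically in every region: genome
#' aberrant somewhere and with discordant per-region states, divided by
#' genome aberrant anywhere.
#'
#' @param states segment-by-region character matrix of copy-number states
#'   (as from [segmentStates()])
#' @param lengths per-segment lengths (equal weights when omitted)
#' @return fraction in \[0, 1\] (NA when no segment is aberrant)
#' @export
scnaITH <- function(states, lengths = NULL) {
    stopifnot(is.matrix(states), ncol(states) >= 2)
    if (is.null(lengths)) lengths <- rep(1, nrow(states))
    aberr <- apply(states != "neutral", 1, any)
    if (!any(aberr)) return(NA_real_)
    het <- apply(states, 1, function(r) length(unique(r)) > 1)
    sum(lengths[aberr & het]) / sum(lengths[aberr])
}

#' Weighted genome instability index of one region
#'
#' Mean over chromosomes of the within-chromosome length fraction with
#' copy number aberrant (gained or lost) relative to the sample ploidy, so
#' every chromosome contributes equally regardless of its length.
#'
#' @param chrom per-segment chromosome identifiers
#' @param lengths per-segment lengths
#' @param totalCN per-segment total copy numbers
#' @param ploidy sample ploidy
#' @return value in \[0, 1\]
#' @export
wgii <- function(chrom, lengths, totalCN, ploidy) {
    st <- segmentStates(totalCN, ploidy)
    aberr <- st != "neutral"
    frac <- vapply(split(seq_along(chrom), chrom), function(i)
        sum(lengths[i][aberr[i]]) / sum(lengths[i]), 0)
    mean(frac)
}

#' Fraction of the genome subject to loss of heterozygosity
#'
#' @param lengths per-segment lengths
#' @param minorCN per-segment minor allele copy numbers
#' @return length fraction with minor copy number 0
#' @export
floh <- function(lengths, minorCN) {
    stopifnot(length(lengths) == length(minorCN))
    if (!sum(lengths)) return(NA_real_)
    sum(lengths[minorCN == 0]) / sum(lengths)
}

#' Recent subclonal expansion score
#'
#' For each region, the maximum PhyloCCF over the leaf (terminal) clusters
#' of the clone tree, clipped per node to \[0, 1\]; the tumour-level score is
#' the maximum of the regional scores, describing the size of the largest
#' recent subclonal expansion. To absorb phylogenetic uncertainty the
#' minimum of the score across all enumerated alternative trees is also
#' reported (alternative trees differ in which clusters are leaves).
#'
#' @param tree a [CloneTree-class]
#' @return list with `score` and `min_over_alternatives`
#' @export
recentExpansionScore <- function(tree) {
    ccf <- clusterCCF(tree)
    scoreOf <- function(parent) {
        nodes <- rownames(ccf)
        leaves <- setdiff(nodes, unique(parent))
        max(apply(pmin(pmax(ccf[leaves, , drop = FALSE], 0), 1), 2, max))
    }
    s <- scoreOf(treeParents(tree))
    alt <- vapply(treeAlternatives(tree), scoreOf, 0)
    list(score = s, min_over_alternatives = min(c(s, alt)))
}

#' Classify detection of the smoking signature SBS4
#'
#' Applies the fixed thresholds on the truncal SBS4 weight and the number of
#' truncal SBS4-assigned mutations: undetected when weight < 0.1 and count
#' < 50; high confidence when weight > 0.3 and count > 20; low confidence
#' otherwise.
#'
#' @param truncalWeight estimated truncal SBS4 weight in \[0, 1\]
#' @param truncalCount number of truncal SBS4-assigned mutations
#' @return one of "undetected", "low_confidence", "high_confidence"
#' @examples
#' classifySBS4(0.05, 30)   # undetected
#' classifySBS4(0.35, 25)   # high_confidence
#' classifySBS4(0.2, 100)   # low_confidence
#' @export
classifySBS4 <- function(truncalWeight, truncalCount) {
    stopifnot(truncalWeight >= 0, truncalWeight <= 1, truncalCount >= 0)
    if (truncalWeight < 0.1 && truncalCount < 50) return("undetected")
    if (truncalWeight > 0.3 && truncalCount > 20) return("high_confidence")
    "low_confidence"
}
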