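#' Mutation copy number from read counts
#'
#' Transforms the variant allele fraction by the tumour purity and the local
#' total copy number: mutCN = (VAF / mu) * (mu * CN_t + 2 * (1 - mu)), i.e.
#' the expected number of mutated copies per cancer cell. Returns NA where
#' total counts are zero.
#'
#' @param var,tot variant and total read counts
#' @param purity tumour purity mu in (0, 1]
#' @param totalCN local total (major + minor) tumour copy number
#' @return numeric mutation copy number(s)
#' @examples
#' mutationCopyNumber(50, 100, 1, 2)   # 1: clonal heterozygous diploid
#' @export
mutationCopyNumber <- function(var, tot, purity, totalCN) {
    stopifnot(all(purity > 0 & purity <= 1))
    vaf <- ifelse(tot > 0, var / tot, NA_real_)
    (vaf / purity) * (purity * totalCN + 2 * (1 - purity))
}

#' Per-mutation PhyloCCF and multiplicity
#'
#' The phylogenetic cancer cell fraction is the fraction of cancer cells
#' that carry (or ancestrally carried, before a subclonal loss) the
#' mutation. It is obtained by dividing the mutation copy number by an
#' integer multiplicity estimate. The multiplicity is the nearest positive
#' integer to the mutation copy number after clipping it at the segment
#' major copy number (a mutation cannot occupy more copies than the larger
#' allele); PhyloCCF values are clipped to \[0, 1.5\].
#'
#' @param mutCN mutation copy number(s), e.g. from [mutationCopyNumber()]
#' @param majorCN segment major copy number(s)
#' @return list with numeric `ccf` and integer `multiplicity`
#' @export
phyloCCF <- function(mutCN, majorCN) {
    mult <- pmax(1L, as.integer(round(pmin(mutCN, majorCN))))
    ccf <- pmin(pmax(mutCN / mult, 0), 1.5)
    list(ccf = ccf, multiplicity = mult)
}

#' Cluster-level PhyloCCF summary with bootstrap CI
#'
#' The cluster value in a region is the mean PhyloCCF over member mutations;
#' the 95% CI is a nonparametric percentile bootstrap over member mutations.
#'
#' @param ccf numeric vector of member-mutation PhyloCCFs in one region
#' @param B bootstrap replicates
#' @return list with `mean`, `lo`, `hi`
#' @export
clusterPhyloCCF <- function(ccf, B = 1000L) {
    ccf <- ccf[!is.na(ccf)]
    if (!length(ccf)) return(list(mean = NA_real_, lo = NA_real_, hi = NA_real_))
    m <- mean(ccf)
    if (length(ccf) == 1L) return(list(mean = m, lo = m, hi = m))
    bs <- vapply(seq_len(B), function(i)
        mean(ccf[sample.int(length(ccf), replace = TRUE)]), 0)
    qs <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
    list(mean = m, lo = qs[1], hi = qs[2])
}

#' Classify a cluster's clonality in one region
#'
#' A cluster is clonal in a region when its member PhyloCCFs are not
#' significantly below the truncal cluster's (one-sided Wilcoxon rank-sum,
#' p > 0.05) or when the 95% CIs of the two clusters overlap, with the
#' truncal CI lower bound capped at 0.9 so that near-clonal clusters
#' reaching 0.9 are rescued. Otherwise the cluster is subclonal when its
#' mean PhyloCCF exceeds 0 (operationally 0.01, absorbing floating noise)
#' and absent when not.
#'
#' @param clusterCCF member-mutation PhyloCCFs of the cluster in the region
#' @param truncalCCF member-mutation PhyloCCFs of the truncal cluster in the
#'   same region
#' @param B bootstrap replicates for the CIs
#' @return one of "clonal", "subclonal", "absent"
#' @export
classifyRegionClonality <- function(clusterCCF, truncalCCF, B = 1000L) {
    truncalCCF <- truncalCCF[!is.na(truncalCCF)]
    if (!length(truncalCCF)) stop("empty truncal cluster")
    clusterCCF <- clusterCCF[!is.na(clusterCCF)]
    if (!length(clusterCCF)) return("absent")
    pv <- suppressWarnings(stats::wilcox.test(
        clusterCCF, truncalCCF, alternative = "less")$p.value)
    if (!is.na(pv) && pv > 0.05) return("clonal")
    ciC <- clusterPhyloCCF(clusterCCF, B)
    ciT <- clusterPhyloCCF(truncalCCF, B)
    loT <- min(ciT$lo, 0.9)
    if (ciC$hi >= loT && ciC$lo <= ciT$hi) return("clonal")
    if (ciC$mean > 0.01) return("subclonal")
    "absent"
}

#' Tumour-level clonality from per-region statuses
#'
#' A cluster is truncal when clonal in every region of interest, absent when
#' absent everywhere and subclonal otherwise. The "illusion of clonality"
#' flags tumour-level subclonal clusters that are nevertheless clonal in at
#' least one region (they would look truncal in a single biopsy).
#'
#' @param statuses character vector of per-region statuses
#'   ("clonal"/"subclonal"/"absent")
#' @return list with `status` ("truncal"/"subclonal"/"absent") and
#'   `illusion` (logical)
#' @export
tumourLevelClonality <- function(statuses) {
    stopifnot(length(statuses) >= 1,
              all(statuses %in% c("clonal", "subclonal", "absent")))
    status <- if (all(statuses == "clonal")) "truncal"
              else if (all(statuses == "absent")) "absent"
              else "subclonal"
    list(status = status,
         illusion = status == "subclonal" && any(statuses == "clonal"))
}

#' Per-mutation PhyloCCF table for a tumour
#'
#' Convenience wrapper joining read counts with per-region segment copy
#' numbers and purity to compute the mutation copy number, multiplicity and
#' PhyloCCF of every mutation in every region.
#'
#' @param reads data.frame with locus, sample_id, var_count, total_count
#' @param segments data.frame with sample_id, arm, major_cn, minor_cn
#' @param samples data.frame with sample_id, purity
#' @param locusArm integer vector mapping each locus to its arm
#' @return `reads` with added columns total_cn, major_cn, mut_cn,
#'   multiplicity, phylo_ccf
#' @export
phyloCCFTable <- function(reads, segments, samples, locusArm) {
    key <- paste(segments$sample_id, segments$arm)
    majorAt <- stats::setNames(segments$major_cn, key)
    minorAt <- stats::setNames(segments$minor_cn, key)
    purityAt <- stats::setNames(samples$purity, samples$sample_id)
    arm <- locusArm[reads$locus]
    k <- paste(reads$sample_id, arm)
    major <- unname(majorAt[k])
    total <- major + unname(minorAt[k])
    ## loci without a segment (e.g. artefacts on a diploid background)
    major[is.na(major)] <- 1
    total[is.na(total)] <- 2
    mu <- unname(purityAt[reads$sample_id])
    mutCN <- mutationCopyNumber(reads$var_count, reads$total_count, mu, total)
    pc <- phyloCCF(mutCN, major)
    reads$total_cn <- total
    reads$major_cn <- major
    reads$mut_cn <- mutCN
    reads$multiplicity <- pc$multiplicity
    reads$phylo_ccf <- pc$ccf
    reads
}
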