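#' Simulation configuration
#'
#' Collects every distribution and rate used by [simulateTumour()] /
#' [simulateCohort()]. Defaults emulate a large multi-region lung-cancer
#' whole-exome cohort: clone counts per sample-size group of 8-16 (low, 2-3
#' samples), 12-24 (medium, 4-7) and 22-30 (high, >7); purity uniform on
#' (0.2, 0.9); mean depth normal around 413x (truncated above 50x); SNV
#' burden negative-binomial (mean 400, size 3) floored above 150; truncal
#' mutation fraction Beta(5, 2) truncated below 0.9; arm-scale SCNAs with
#' Poisson counts per edge; an optional truncal WGD and 0-3 subclonal WGDs
#' on distinct non-trunk edges; artefact SNVs at 1% of the mutation burden.
#' Every cohort-level constraint (purity > 0.20, > 150 SNVs, truncal
#' proportion < 0.90) is enforced by rejection.
#'
#' @param sampleGroupProbs named probabilities for the low/medium/high
#'   sample-size groups
#' @param nSamplesRange named list of sample-count ranges per group
#' @param purityRange min/max of the per-sample purity distribution
#' @param coverageMean,coverageSD,coverageFloor coverage distribution
#' @param snvMean,snvSize,snvFloor negative-binomial SNV burden and floor
#' @param truncalShape Beta shape parameters of the truncal fraction
#' @param truncalMax upper truncation of the truncal fraction
#' @param nArms,armLength number and length (bp) of chromosome-arm segments
#' @param scnaTrunkRate,scnaEdgeRate,gainProb SCNA placement parameters
#' @param truncalWGDProb probability of a truncal WGD
#' @param subWGDProbs probabilities of 0, 1, 2, 3 subclonal WGD events
#' @param artefactRate artefact loci per SNV (count = round(rate * nSnvs))
#' @param nClonesRange optional integer range overriding the group clone
#'   ranges (e.g. `5:8` for small, well-separated test tumours)
#' @param nSamplesFixed optional fixed sample count override
#' @param coverageFixed optional fixed coverage override
#' @param minCCFGap reject tumours whose sampled-clone CCF vectors are closer
#'   than this in L-infinity distance (0 disables; used for well-separated
#'   evaluation scenarios)
#' @return object of class `SimConfig` (a validated list)
#' @examples
#' cfg <- simConfig()
#' cfg$truncalWGDProb
#' @export
simConfig <- function(sampleGroupProbs = c(low = 0.45, medium = 0.45, high = 0.10),
                      nSamplesRange = list(low = 2:3, medium = 4:7, high = 8:10),
                      purityRange = c(0.2, 0.9),
                      coverageMean = 413, coverageSD = 60, coverageFloor = 50,
                      snvMean = 400, snvSize = 3, snvFloor = 150,
                      truncalShape = c(5, 2), truncalMax = 0.9,
                      nArms = 44L, armLength = 5e7,
                      scnaTrunkRate = 3, scnaEdgeRate = 0.6, gainProb = 0.5,
                      truncalWGDProb = 0.25,
                      subWGDProbs = c(0.25, 0.25, 0.25, 0.25),
                      artefactRate = 0.01,
                      nClonesRange = NULL, nSamplesFixed = NULL,
                      coverageFixed = NULL, minCCFGap = 0) {
    stopifnot(abs(sum(sampleGroupProbs) - 1) < 1e-8,
              all(names(sampleGroupProbs) %in% c("low", "medium", "high")),
              purityRange[1] >= 0.2, length(subWGDProbs) == 4L)
    cfg <- list(
        sampleGroupProbs = sampleGroupProbs, nSamplesRange = nSamplesRange,
        purityRange = purityRange, coverageMean = coverageMean,
        coverageSD = coverageSD, coverageFloor = coverageFloor,
        snvMean = snvMean, snvSize = snvSize, snvFloor = snvFloor,
        truncalShape = truncalShape, truncalMax = truncalMax,
        nArms = as.integer(nArms), armLength = armLength,
        scnaTrunkRate = scnaTrunkRate, scnaEdgeRate = scnaEdgeRate,
        gainProb = gainProb, truncalWGDProb = truncalWGDProb,
        subWGDProbs = subWGDProbs / sum(subWGDProbs),
        artefactRate = artefactRate,
        nClonesRange = nClonesRange, nSamplesFixed = nSamplesFixed,
        coverageFixed = coverageFixed, minCCFGap = minCCFGap)
    class(cfg) <- "SimConfig"
    cfg
}

## truncated draws -------------------------------------------------------

#' @noRd
drawCoverage <- function(cfg) {
    if (!is.null(cfg$coverageFixed)) return(cfg$coverageFixed)
    repeat {
        g <- stats::rnorm(1, cfg$coverageMean, cfg$coverageSD)
        if (g > cfg$coverageFloor) return(g)
    }
}

#' @noRd
drawSnvCount <- function(cfg) {
    repeat {
        n <- stats::rnbinom(1, mu = cfg$snvMean, size = cfg$snvSize)
        if (n > cfg$snvFloor) return(n)
    }
}

#' @noRd
drawTruncalFraction <- function(cfg) {
    repeat {
        f <- stats::rbeta(1, cfg$truncalShape[1], cfg$truncalShape[2])
        if (f < cfg$truncalMax) return(f)
    }
}

#' Per-region cancer cell fraction of every clone
#'
#' The CCF of clone i in sample s is the fraction of cancer cells in s that
#' descend from i (including i itself): sum of u over the subtree of i.
#'
#' @param phylo a [ClonePhylogeny-class]
#' @param proportions clone-by-sample proportion matrix
#' @return clone-by-sample CCF matrix
#' @export
cloneCCFMatrix <- function(phylo, proportions) {
    clones <- as.integer(rownames(proportions))
    ccf <- proportions * 0
    for (i in seq_along(clones)) {
        d <- as.character(descendantsOf(phylo, clones[i]))
        ccf[i, ] <- colSums(proportions[d, , drop = FALSE])
    }
    ccf
}

#' Simulate one multi-region tumour
#'
#' Runs the four simulation stages end to end for a single tumour: random
#' topology, event assignment (SNVs, SCNAs, WGDs), genotype propagation,
#' Dirichlet bulk mixing, Poisson/Binomial read counts and artefact
#' injection. Per-sample allele-specific arm copy numbers are reported as a
#' copy-number caller would: the clone-proportion-weighted allele copy
#' numbers of the cancer cells, rounded to integers.
#'
#' Consumes the R random number stream; seed at the call site (or use
#' [simulateCohort()]).
#'
#' @param config a [simConfig()] object
#' @param tumourId identifier stored in the output tables
#' @return a [SimulatedTumour-class]
#' @examples
#' set.seed(7)
#' tum <- simulateTumour(simConfig())
#' tum
#' @export
simulateTumour <- function(config = simConfig(), tumourId = "T1") {
    stopifnot(inherits(config, "SimConfig"))
    repeat {
        tum <- .simulateTumourOnce(config, tumourId)
        if (is.null(tum)) next
        ## cohort constraints (guaranteed by the truncated draws for the
        ## default config, re-checked so overrides stay honest)
        nSnv <- sum(tum@events$kind == "SNV")
        truncalProp <- sum(tum@events$kind == "SNV" &
                           tum@events$child == tum@phylogeny@mrca) / nSnv
        if (all(tum@samples$purity > 0.20) && nSnv > 150 && truncalProp < 0.90)
            return(tum)
    }
}

#' @noRd
.simulateTumourOnce <- function(cfg, tumourId) {
    group <- sample(names(cfg$sampleGroupProbs), 1L,
                    prob = cfg$sampleGroupProbs)
    nSamples <- if (!is.null(cfg$nSamplesFixed)) cfg$nSamplesFixed else {
        r <- cfg$nSamplesRange[[group]]
        if (length(r) == 1L) r else sample(r, 1L)
    }
    nClo <- if (!is.null(cfg$nClonesRange)) {
        r <- cfg$nClonesRange
        if (length(r) == 1L) r else sample(r, 1L)
    } else drawCloneCount(group)
    phylo <- simulateTopology(nClo)
    purity <- stats::runif(nSamples, cfg$purityRange[1], cfg$purityRange[2])
    coverage <- vapply(seq_len(nSamples), function(i) drawCoverage(cfg), 0)
    nSnvs <- drawSnvCount(cfg)
    truncalFraction <- drawTruncalFraction(cfg)
    ## WGD placement
    wgdChildren <- integer(0)
    if (stats::runif(1) < cfg$truncalWGDProb)
        wgdChildren <- phylo@mrca
    sub <- subclonalEdgeChildren(phylo)
    nSub <- sample(0:3, 1L, prob = cfg$subWGDProbs)
    nSub <- min(nSub, length(sub))
    if (nSub > 0)
        wgdChildren <- c(wgdChildren, sample(sub, nSub))
    events <- assignEvents(phylo, nSnvs, truncalFraction,
                           nArms = cfg$nArms,
                           scnaTrunkRate = cfg$scnaTrunkRate,
                           scnaEdgeRate = cfg$scnaEdgeRate,
                           gainProb = cfg$gainProb,
                           wgdChildren = wgdChildren)
    geno <- propagateGenotypes(phylo, events, nArms = cfg$nArms)
    bulk <- sampleBulk(phylo, nSamples, purity, coverage)
    ccfClone <- cloneCCFMatrix(phylo, bulk$proportions)
    if (cfg$minCCFGap > 0) {
        present <- rowSums(ccfClone) > 0
        cc <- ccfClone[present, , drop = FALSE]
        if (nrow(cc) > 1) {
            dm <- as.matrix(stats::dist(cc, method = "maximum"))
            if (min(dm[upper.tri(dm)]) < cfg$minCCFGap) return(NULL)
        }
    }
    reads <- do.call(rbind, lapply(seq_len(nSamples), function(s) {
        r <- generateReads(bulk$proportions[, s], geno,
                           purity[s], coverage[s])
        r$sample_id <- bulk$samples$sample_id[s]
        r
    }))
    reads$is_artefact <- FALSE
    nArt <- round(cfg$artefactRate * nSnvs)
    reads <- injectArtefacts(reads, bulk$samples, bulk$proportions, nArt)
    reads$tumour_id <- tumourId
    segs <- .bulkSegments(cfg, geno, bulk, tumourId)
    snv <- events[events$kind == "SNV", ]
    truth <- list(
        cloneCCF = ccfClone,
        clusterOf = stats::setNames(snv$child, snv$locus),
        locusArm = geno$locusArm,
        wgd = .wgdTruth(phylo, events, ccfClone)
    )
    rownames(reads) <- NULL
    new("SimulatedTumour", phylogeny = phylo, events = events,
        genotypes = geno, samples = bulk$samples,
        proportions = bulk$proportions, readCounts = reads,
        segments = segs, truth = truth)
}

#' @noRd
.bulkSegments <- function(cfg, geno, bulk, tumourId) {
    U <- bulk$proportions
    out <- lapply(seq_len(ncol(U)), function(s) {
        u <- U[, s]
        cl <- names(u)[u > 0]
        A <- round(as.numeric(geno$x[, cl, drop = FALSE] %*% u[cl]))
        B <- round(as.numeric(geno$y[, cl, drop = FALSE] %*% u[cl]))
        arm <- seq_len(cfg$nArms)
        chrom <- ceiling(arm / 2)
        isQ <- arm %% 2 == 0
        data.frame(
            tumour_id = tumourId, sample_id = colnames(U)[s],
            chrom = chrom,
            start = ifelse(isQ, cfg$armLength + 1, 1),
            end = ifelse(isQ, 2 * cfg$armLength, cfg$armLength),
            arm = arm,
            major_cn = pmax(A, B), minor_cn = pmin(A, B),
            stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' @noRd
.wgdTruth <- function(phylo, events, ccfClone) {
    wg <- events[events$kind == "WGD", , drop = FALSE]
    if (!nrow(wg))
        return(data.frame(event_id = character(0), child = integer(0),
                          truncal = logical(0)))
    ccf <- ccfClone[as.character(wg$child), , drop = FALSE]
    out <- data.frame(
        event_id = paste0("WGD", seq_len(nrow(wg))),
        child = wg$child,
        truncal = wg$child == phylo@mrca,
        stringsAsFactors = FALSE)
    cbind(out, as.data.frame(ccf))
}

#' Simulate a cohort of tumours
#'
#' Repeatedly calls [simulateTumour()]; every emitted tumour satisfies the
#' cohort constraints (purity > 0.20 in all samples, > 150 somatic SNVs,
#' truncal proportion < 0.90). A fixed seed gives an identical cohort on
#' rerun. An error is raised if the acceptance rate drops below 1% over
#' 10,000 attempts (degenerate configuration).
#'
#' @param config a [simConfig()] object
#' @param n number of tumours
#' @param seed optional integer seed
#' @return list of [SimulatedTumour-class] objects, named by tumour id
#' @export
simulateCohort <- function(config = simConfig(), n = 10, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    attempts <- 0L
    out <- vector("list", n)
    for (i in seq_len(n)) {
        repeat {
            attempts <- attempts + 1L
            if (attempts >= 10000L && (i - 1) / attempts < 0.01)
                stop("configuration error: cohort acceptance rate below 1%")
            tum <- .simulateTumourOnce(config, sprintf("T%03d", i))
            if (is.null(tum)) next
            nSnv <- sum(tum@events$kind == "SNV")
            tp <- sum(tum@events$kind == "SNV" &
                      tum@events$child == tum@phylogeny@mrca) / nSnv
            if (all(tum@samples$purity > 0.20) && nSnv > 150 && tp < 0.90)
                break
        }
        out[[i]] <- tum
    }
    names(out) <- vapply(out, function(t) t@readCounts$tumour_id[1], "")
    out
}
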