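#' Region-count baselines for subclonal WGD detection
#'
#' The "NEJM" baseline calls a subclonal WGD when some but not all regions
#' of a tumour harbour a detected WGD (non-uniform per-region counts); it
#' can never distinguish more than one subclonal event. The "NEJM 2nd WGD"
#' variant counts one subclonal event per distinct WGD-count level above the
#' minimum observed level (so regions at 0, 1 and 2 WGDs yield two
#' subclonal events).
#'
#' @param regionCounts integer vector of per-region WGD counts
#' @return list with `nejm_subclonal` (logical) and `nejm2_n_subclonal`
#'   (integer)
#' @examples
#' baselineNEJM(c(1, 1, 1))   # no subclonal WGD
#' baselineNEJM(c(2, 1, 0))   # two subclonal events under NEJM 2nd WGD
#' @export
baselineNEJM <- function(regionCounts) {
    stopifnot(length(regionCounts) >= 1, all(regionCounts >= 0))
    lev <- unique(regionCounts)
    list(nejm_subclonal = length(lev) > 1L,
         nejm2_n_subclonal = length(setdiff(lev, min(regionCounts))))
}

#' Mark which true WGD events are detectable
#'
#' A WGD event restricted to a minority of cells in every sampled region is
#' not recoverable from bulk mutation copy numbers. An event is marked
#' detectable when its clone reaches a CCF above 0.75 in some region, or
#' when it lies in a region where the summed CCFs of parallel WGD events
#' (events on branches where neither is ancestral to the other) exceed
#' 0.75.
#'
#' @param tumour a [SimulatedTumour-class]
#' @return the tumour's WGD truth table with added columns `detectable` and
#'   a `"nDetectableSubclonal"` attribute
#' @export
markDetectable <- function(tumour) {
    wgd <- tumour@truth$wgd
    regions <- colnames(tumour@proportions)
    if (!nrow(wgd)) {
        attr(wgd, "nDetectableSubclonal") <- 0L
        return(wgd)
    }
    ccf <- as.matrix(wgd[, regions, drop = FALSE])
    n <- nrow(wgd)
    ## parallel = neither event's clone is an ancestor of the other's
    par <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
        ai <- c(wgd$child[i], ancestorsOf(tumour@phylogeny, wgd$child[i]))
        aj <- c(wgd$child[j], ancestorsOf(tumour@phylogeny, wgd$child[j]))
        par[i, j] <- !(wgd$child[j] %in% ai) && !(wgd$child[i] %in% aj)
    }
    detectable <- logical(n)
    for (i in seq_len(n)) {
        if (any(ccf[i, ] > 0.75)) { detectable[i] <- TRUE; next }
        grp <- c(i, which(par[i, ]))
        sums <- colSums(ccf[grp, , drop = FALSE])
        detectable[i] <- any(ccf[i, ] > 0 & sums > 0.75)
    }
    wgd$detectable <- detectable
    attr(wgd, "nDetectableSubclonal") <- sum(detectable & !wgd$truncal)
    wgd
}

#' Ground-truth-detectable WGD counts per region
#'
#' The number of detectable true WGD events whose clone sweeps each region
#' (CCF > 0.75), capped at two per region; this is the per-region count the
#' detector and the baselines receive as input during validation.
#'
#' @param tumour a [SimulatedTumour-class]
#' @param wgd marked truth table from [markDetectable()]
#' @return named integer vector over regions
#' @export
truthRegionCounts <- function(tumour, wgd = markDetectable(tumour)) {
    regions <- colnames(tumour@proportions)
    counts <- stats::setNames(integer(length(regions)), regions)
    for (i in seq_len(nrow(wgd))) {
        if (!wgd$detectable[i]) next
        swept <- as.numeric(wgd[i, regions]) > 0.75
        counts[swept] <- counts[swept] + 1L
    }
    pmin(counts, 2L)
}

#' Sensitivity and specificity of multiple-subclonal-WGD calls
#'
#' Positive class: the tumour truly harbours at least two detectable
#' subclonal WGD events. Sensitivity = TP / (TP + FN), specificity =
#' TN / (TN + FP).
#'
#' @param calls logical vector of per-tumour positive calls
#' @param truthPos logical vector of per-tumour truth
#' @return list with sensitivity, specificity, TP, FP, TN, FN
#' @export
evaluateCalls <- function(calls, truthPos) {
    if (length(calls) != length(truthPos))
        stop("invalid-argument: calls and truth refer to different tumour sets")
    TP <- sum(calls & truthPos); FN <- sum(!calls & truthPos)
    TN <- sum(!calls & !truthPos); FP <- sum(calls & !truthPos)
    list(sensitivity = if (TP + FN) TP / (TP + FN) else NA_real_,
         specificity = if (TN + FP) TN / (TN + FP) else NA_real_,
         TP = TP, FP = FP, TN = TN, FN = FN)
}

#' Mutation table for the WGD detector from a simulated tumour
#'
#' One row per (non-artefact) mutation per region with the cluster identity
#' and mutation copy number. By default mutation copy numbers are estimated
#' from the simulated read counts via [mutationCopyNumber()]; with
#' `noiseless = TRUE` the exact value sum_i u_i z_ip is used instead
#' (genotype truth, no read noise).
#'
#' @param tumour a [SimulatedTumour-class]
#' @param noiseless use exact genotype-derived mutation copy numbers
#' @param trueClusters use the true mutation cluster identities (the edge on
#'   which each SNV arose); FALSE requires clustering upstream and is not
#'   provided here
#' @return data.frame with mutation, sample_id, cluster, mut_cn, major_cn
#' @export
detectorInput <- function(tumour, noiseless = FALSE, trueClusters = TRUE) {
    stopifnot(trueClusters)
    geno <- tumour@genotypes
    segs <- tumour@segments
    reads <- tumour@readCounts[!tumour@readCounts$is_artefact, , drop = FALSE]
    tab <- phyloCCFTable(reads, segs, tumour@samples, geno$locusArm)
    if (noiseless) {
        U <- tumour@proportions
        exact <- geno$z %*% U            # loci x samples: sum_i u_i z_ip
        tab$mut_cn <- exact[cbind(tab$locus,
                                  match(tab$sample_id, colnames(U)))]
    }
    data.frame(mutation = tab$locus, sample_id = tab$sample_id,
               cluster = as.character(
                   tumour@truth$clusterOf[as.character(tab$locus)]),
               mut_cn = tab$mut_cn, major_cn = tab$major_cn,
               stringsAsFactors = FALSE)
}

#' Run all three WGD-detection methods on one simulated tumour
#'
#' @param tumour a [SimulatedTumour-class]
#' @param noiseless passed to [detectorInput()]
#' @return list with `truth_pos`, `n_detectable_subclonal`, per-method
#'   positive calls, the detector [WGDEventSet-class] and the region counts
#' @export
benchmarkTumour <- function(tumour, noiseless = FALSE) {
    wgd <- markDetectable(tumour)
    counts <- truthRegionCounts(tumour, wgd)
    base <- baselineNEJM(counts)
    ev <- detectWGD(detectorInput(tumour, noiseless = noiseless),
                    counts, as.character(tumour@phylogeny@mrca))
    nSub <- sum(wgdEvents(ev)$clonality == "subclonal")
    list(
        truth_pos = attr(wgd, "nDetectableSubclonal") >= 2L,
        n_detectable_subclonal = attr(wgd, "nDetectableSubclonal"),
        call_parallelgd = nSub >= 2L,
        call_nejm = FALSE,      # single-event method: never calls >= 2
        call_nejm2 = base$nejm2_n_subclonal >= 2L,
        nejm_any_subclonal = base$nejm_subclonal,
        n_subclonal_called = nSub,
        events = ev, region_counts = counts)
}

#' Simulation benchmark of the WGD detector against region-count baselines
#'
#' Simulates a cohort, derives the ground-truth detectable subclonal WGD
#' events, runs the doubled-cluster detector and both region-count baselines
#' on every tumour, and scores sensitivity and specificity for the task of
#' calling two or more subclonal WGD events.
#'
#' @param config a [simConfig()] object
#' @param n number of tumours
#' @param seed integer seed (the whole benchmark is reproducible)
#' @param noiseless use exact mutation copy numbers instead of read-derived
#' @return list with `results` (one row per method: sensitivity,
#'   specificity, confusion counts) and `audit` (one row per tumour)
#' @examples
#' \donttest{
#' bm <- runBenchmark(simConfig(), n = 50, seed = 1)
#' bm$results
#' }
#' @export
runBenchmark <- function(config = simConfig(), n = 500, seed = 1,
                         noiseless = FALSE) {
    set.seed(seed)
    audit <- vector("list", n)
    for (i in seq_len(n)) {
        tum <- simulateTumour(config, sprintf("T%03d", i))
        b <- benchmarkTumour(tum, noiseless = noiseless)
        audit[[i]] <- data.frame(
            tumour_id = sprintf("T%03d", i),
            truth_pos = b$truth_pos,
            n_detectable_subclonal = b$n_detectable_subclonal,
            call_parallelgd = b$call_parallelgd,
            call_nejm = b$call_nejm,
            call_nejm2 = b$call_nejm2,
            n_subclonal_called = b$n_subclonal_called,
            stringsAsFactors = FALSE)
    }
    audit <- do.call(rbind, audit)
    methods <- c(parallelgd = "call_parallelgd", nejm = "call_nejm",
                 nejm2 = "call_nejm2")
    results <- do.call(rbind, lapply(names(methods), function(m) {
        e <- evaluateCalls(audit[[methods[[m]]]], audit$truth_pos)
        data.frame(method = m, sensitivity = e$sensitivity,
                   specificity = e$specificity, TP = e$TP, FP = e$FP,
                   TN = e$TN, FN = e$FN, n_tumours = n,
                   stringsAsFactors = FALSE)
    }))
    list(results = results, audit = audit)
}
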