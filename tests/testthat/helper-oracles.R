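## Independent oracles and fixture builders used across the test files.
## Everything here is implemented directly from the rule statements, on
## purpose NOT sharing code with the package internals it checks.

## Brute-force enumeration of all valid clone trees: every assignment of a
## parent to each non-trunk cluster, filtered by direct checks of
## rootedness, the crossing rule and the pigeonhole principle.
bruteForceTrees <- function(ccf, trunk, tol = 0.1) {
    ids <- rownames(ccf)
    free <- setdiff(ids, trunk)
    if (!length(free)) return(list(stats::setNames(character(0), character(0))))
    choices <- lapply(free, function(v) setdiff(ids, v))
    grid <- expand.grid(choices, stringsAsFactors = FALSE)
    out <- list()
    for (i in seq_len(nrow(grid))) {
        parent <- stats::setNames(as.character(unlist(grid[i, ])), free)
        ## rooted & acyclic: repeated parent-steps from each node hit trunk
        ok <- TRUE
        anc <- list()
        for (v in free) {
            chain <- character(0)
            cur <- v
            for (step in seq_len(length(ids) + 1)) {
                if (cur == trunk) break
                cur <- parent[[cur]]
                chain <- c(chain, cur)
            }
            if (cur != trunk) { ok <- FALSE; break }
            anc[[v]] <- setdiff(chain, trunk)
        }
        if (!ok) next
        ## crossing rule
        for (v in free) for (a in anc[[v]])
            if (any(ccf[a, ] < ccf[v, ] - tol)) { ok <- FALSE; break }
        if (!ok) next
        ## pigeonhole
        for (pa in unique(parent)) {
            ch <- free[parent == pa]
            if (any(colSums(ccf[ch, , drop = FALSE]) > ccf[pa, ] + tol)) {
                ok <- FALSE; break
            }
        }
        if (ok) out[[length(out) + 1L]] <- parent
    }
    out
}

treeKey <- function(parent) {
    if (!length(parent)) return("")
    paste(paste(names(parent), parent, sep = ">")[order(names(parent))],
          collapse = "|")
}

## Random cluster CCF matrix with a guaranteed dominating trunk.
randomClusterCCF <- function(nClusters, nRegions) {
    ccf <- matrix(round(runif((nClusters - 1) * nRegions), 2),
                  nClusters - 1, nRegions)
    ccf <- rbind(rep(1, nRegions), ccf)
    rownames(ccf) <- c("trunk", paste0("C", seq_len(nClusters - 1)))
    colnames(ccf) <- paste0("R", seq_len(nRegions))
    ccf
}

## Build a ClonePhylogeny from a child -> parent map given as two vectors.
makePhylo <- function(children, parents) {
    p <- stats::setNames(as.integer(parents), as.character(children))
    methods::new("ClonePhylogeny", parent = p, germlineRoot = 0L,
                 mrca = as.integer(children[parents == 0]))
}

## Hand-build an events table (same columns as assignEvents output).
makeEvents <- function(kind, child, locus = NA, arm = NA, allele = NA,
                       magnitude = NA, phylo) {
    n <- max(length(kind), length(child))
    kind <- rep_len(kind, n)
    child <- rep_len(child, n)
    p <- cloneParents(phylo)
    ev <- data.frame(kind = kind, parent = unname(p[as.character(child)]),
                     child = as.integer(child),
                     locus = as.integer(rep_len(locus, n)),
                     arm = as.integer(rep_len(arm, n)),
                     allele = as.character(rep_len(allele, n)),
                     magnitude = as.integer(rep_len(magnitude, n)),
                     stringsAsFactors = FALSE)
    ev$order_index <- stats::ave(seq_len(n), ev$child, FUN = seq_along)
    ev
}

## Manually assembled SimulatedTumour with fixed clone proportions per
## region (columns of `U` must sum to 1), exact rounded bulk segments and
## Poisson/Binomial reads. Used for clean-sweep WGD oracle scenarios.
makeManualTumour <- function(phylo, events, U, purity = 1, coverage = 400,
                             nArms = 44L, id = "TM") {
    geno <- propagateGenotypes(phylo, events, nArms = nArms)
    samples <- data.frame(sample_id = colnames(U),
                          purity = rep_len(purity, ncol(U)),
                          coverage = rep_len(coverage, ncol(U)),
                          stringsAsFactors = FALSE)
    reads <- do.call(rbind, lapply(seq_len(ncol(U)), function(s) {
        r <- generateReads(U[, s], geno, samples$purity[s],
                           samples$coverage[s])
        r$sample_id <- samples$sample_id[s]
        r
    }))
    reads$is_artefact <- FALSE
    reads$tumour_id <- id
    segs <- do.call(rbind, lapply(seq_len(ncol(U)), function(s) {
        u <- U[, s]
        cl <- names(u)[u > 0]
        A <- round(as.numeric(geno$x[, cl, drop = FALSE] %*% u[cl]))
        B <- round(as.numeric(geno$y[, cl, drop = FALSE] %*% u[cl]))
        arm <- seq_len(nArms)
        data.frame(tumour_id = id, sample_id = colnames(U)[s],
                   chrom = ceiling(arm / 2),
                   start = ifelse(arm %% 2 == 0, 5e7 + 1, 1),
                   end = ifelse(arm %% 2 == 0, 1e8, 5e7),
                   arm = arm, major_cn = pmax(A, B), minor_cn = pmin(A, B),
                   stringsAsFactors = FALSE)
    }))
    snv <- events[events$kind == "SNV", ]
    ccfClone <- cloneCCFMatrix(phylo, U)
    methods::new("SimulatedTumour", phylogeny = phylo, events = events,
                 genotypes = geno, samples = samples, proportions = U,
                 readCounts = reads, segments = segs,
                 truth = list(cloneCCF = ccfClone,
                              clusterOf = stats::setNames(snv$child, snv$locus),
                              locusArm = geno$locusArm,
                              wgd = cloneGD:::.wgdTruth(phylo, events, ccfClone)))
}

## Configuration for the well-separated parameter-recovery scenario:
## small trees, four regions, high depth, no artefacts, clones kept at
## least 0.2 apart in CCF space.
recoveryConfig <- function() {
    simConfig(nClonesRange = 5:8, nSamplesFixed = 4L, coverageFixed = 400,
              purityRange = c(0.5, 0.9), minCCFGap = 0.2, artefactRate = 0,
              scnaTrunkRate = 2, scnaEdgeRate = 0.3,
              truncalWGDProb = 0, subWGDProbs = c(1, 0, 0, 0))
}

## True parent map of a tumour restricted to the clusters present in `cls`
## (each cluster's parent is its nearest retained ancestor, else the trunk).
trueParentMap <- function(tum, cls) {
    trunk <- mrcaClone(tum@phylogeny)
    p <- cloneParents(tum@phylogeny)
    anc <- function(v) {
        out <- integer(0); cur <- v
        repeat {
            pa <- p[[as.character(cur)]]
            if (pa == 0) break
            out <- c(out, pa); cur <- pa
        }
        out
    }
    free <- setdiff(cls, trunk)
    pm <- vapply(free, function(c2) {
        a <- anc(c2)
        a <- a[a %in% cls]
        as.character(if (length(a)) a[1] else trunk)
    }, "")
    stats::setNames(pm, as.character(free))
}

## Estimated per-mutation PhyloCCF matrix (mutations x regions) of the
## observable (non-artefact, somewhere-present) loci of a tumour, plus the
## matching truth labels.
recoveryInput <- function(tum) {
    reads <- tum@readCounts[!tum@readCounts$is_artefact, , drop = FALSE]
    tab <- phyloCCFTable(reads, tum@segments, tum@samples,
                         tum@genotypes$locusArm)
    regions <- tum@samples$sample_id
    ccf <- do.call(cbind, lapply(regions, function(r) {
        rr <- tab[tab$sample_id == r, ]
        rr$phylo_ccf[order(rr$locus)]
    }))
    vc <- do.call(cbind, lapply(regions, function(r) {
        rr <- tab[tab$sample_id == r, ]
        rr$var_count[order(rr$locus)]
    }))
    loci <- sort(unique(tab$locus))
    dimnames(ccf) <- dimnames(vc) <- list(loci, regions)
    keep <- rowSums(vc) > 0          # unobservable mutations are never called
    list(ccf = ccf[keep, , drop = FALSE], varCounts = vc[keep, , drop = FALSE],
         truthCluster = tum@truth$clusterOf[rownames(ccf)[keep]])
}
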