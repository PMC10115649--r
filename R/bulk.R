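#' Simulate heterogeneous bulk tumour samples
#'
#' Each bulk sample contains cells of `nHat` distinct tumour clones, with
#' `nHat` drawn uniformly from {3, ..., 8} (clamped to the number of clones
#' available) and the clones chosen uniformly at random. Clone proportions
#' over the chosen clones follow a flat Dirichlet distribution,
#' u ~ Dirichlet(1), so they always sum to one over the cancer cells; the
#' remaining 1 - purity of the sample is normal diploid cells.
#'
#' @param phylo a [ClonePhylogeny-class]
#' @param nSamples number of bulk samples (regions)
#' @param purity numeric vector of per-sample purities (recycled)
#' @param coverage numeric vector of expected mean coverages (recycled)
#' @return list with `samples` (data.frame sample_id, purity, coverage) and
#'   `proportions` (clone-by-sample matrix; zero rows for absent clones,
#'   columns sum to 1)
#' @examples
#' set.seed(1)
#' ph <- simulateTopology(6)
#' b <- sampleBulk(ph, 3, purity = 0.6, coverage = 400)
#' colSums(b$proportions)
#' @export
sampleBulk <- function(phylo, nSamples, purity, coverage = 400) {
    stopifnot(is(phylo, "ClonePhylogeny"))
    if (!is.numeric(nSamples) || nSamples < 1)
        stop("'nSamples' must be a positive integer")
    nSamples <- as.integer(nSamples)
    clones <- sort(as.integer(names(cloneParents(phylo))))
    purity <- rep_len(purity, nSamples)
    coverage <- rep_len(coverage, nSamples)
    U <- matrix(0, length(clones), nSamples,
                dimnames = list(clones, paste0("R", seq_len(nSamples))))
    for (s in seq_len(nSamples)) {
        nHat <- min(sample(3:8, 1L), length(clones))
        chosen <- if (length(clones) == 1L) clones else sample(clones, nHat)
        u <- stats::rgamma(nHat, shape = 1)    # flat Dirichlet via Gamma(1)
        U[as.character(chosen), s] <- u / sum(u)
    }
    list(
        samples = data.frame(
            sample_id = colnames(U), purity = purity, coverage = coverage,
            stringsAsFactors = FALSE),
        proportions = U
    )
}

#' Fractional copy number and sample ploidy of a bulk sample
#'
#' The fractional copy number of a locus is the clone-proportion-weighted
#' average total copy number across the cancer cells of the sample,
#' f_p = sum_i u_i (x_ip + y_ip), and the sample ploidy rho is the mean of
#' f over the (equally weighted) chromosome arms.
#'
#' @param u clone-proportion vector (named by clone id, summing to 1)
#' @param genotypes output of [propagateGenotypes()]
#' @return list with `fArm` (per-arm fractional CN), `fLocus` (per-SNV-locus
#'   fractional CN), `mutArm` (per-arm weighted mutant-allele CN is not
#'   included; see [expectedVAF()]) and `rho` (sample ploidy)
#' @export
computeSampleState <- function(u, genotypes) {
    cl <- names(u)[u > 0]
    uu <- u[cl]
    xa <- genotypes$x[, cl, drop = FALSE]
    ya <- genotypes$y[, cl, drop = FALSE]
    fArm <- as.numeric((xa + ya) %*% uu)
    rho <- mean(fArm)
    fLocus <- if (length(genotypes$locusArm)) fArm[genotypes$locusArm] else numeric(0)
    list(fArm = fArm, fLocus = fLocus, rho = rho)
}

#' Expected variant allele fraction of every SNV locus in a sample
#'
#' psi is the fraction of all sequenced alleles at the locus that carry the
#' variant, across the whole cell population: the mutant copies contributed
#' by cancer cells, mu * sum_i u_i z_ip, over the total copies contributed by
#' cancer cells and the 1 - mu normal diploid cells,
#' mu * f_p + 2 (1 - mu). At purity mu = 1 this reduces to
#' sum(u z) / sum(u (x + y)).
#'
#' @param u clone proportions (named, summing to 1)
#' @param genotypes output of [propagateGenotypes()]
#' @param purity sample purity mu in \[0, 1\]
#' @return numeric vector of per-locus psi in \[0, 1\]
#' @export
expectedVAF <- function(u, genotypes, purity) {
    st <- computeSampleState(u, genotypes)
    cl <- names(u)[u > 0]
    zz <- genotypes$z[, cl, drop = FALSE]
    mutCopies <- if (nrow(zz)) as.numeric(zz %*% u[cl]) else numeric(0)
    denom <- purity * st$fLocus + 2 * (1 - purity)
    psi <- ifelse(denom > 0, purity * mutCopies / denom, 0)
    if (any(psi < -1e-12 | psi > 1 + 1e-12))
        stop("internal consistency error: psi outside [0, 1]")
    pmin(pmax(psi, 0), 1)
}

#' Generate read counts for one bulk sample
#'
#' Total reads at locus p are Poisson with mean proportional to the locus's
#' cell-population fractional copy number relative to the cell-population
#' ploidy times the expected coverage: t_p ~ Poisson(fc_p / rho_c * gamma),
#' with fc = mu f + 2(1 - mu) and rho_c its mean over arms. Variant reads
#' are Binomial: v_p ~ Binomial(t_p, psi_p). At purity 1 the Poisson mean is
#' the printed (f / rho) gamma.
#'
#' @inheritParams expectedVAF
#' @param coverage expected mean coverage gamma (> 0)
#' @return data.frame with locus, total_count, var_count, psi
#' @export
generateReads <- function(u, genotypes, purity, coverage) {
    stopifnot(coverage > 0)
    st <- computeSampleState(u, genotypes)
    if (st$rho <= 0) stop("sample ploidy must be positive")
    fc <- purity * st$fLocus + 2 * (1 - purity)
    rhoc <- purity * st$rho + 2 * (1 - purity)
    psi <- expectedVAF(u, genotypes, purity)
    nLoci <- length(fc)
    t <- stats::rpois(nLoci, fc / rhoc * coverage)
    v <- stats::rbinom(nLoci, t, psi)
    data.frame(locus = seq_len(nLoci), total_count = t, var_count = v,
               psi = psi)
}

#' Inject artefactual mutations into a tumour's read counts
#'
#' Appends `nArtefacts` artefact loci whose expected VAF in each sample is
#' computed from freshly drawn, per-sample-independent clone proportions (and
#' an independent per-sample clone carrier pattern), so artefacts violate the
#' consistency of the clone tree across samples. Artefacts sit on a diploid
#' background. Original loci are untouched.
#'
#' @param readCounts data.frame of read counts with columns locus, sample_id,
#'   total_count, var_count, psi (long format, as built by [simulateTumour()])
#' @param samples per-sample data.frame (sample_id, purity, coverage)
#' @param proportions clone-by-sample proportion matrix (used only for the
#'   identity of the clones present per sample)
#' @param nArtefacts number of artefact loci to append (>= 0)
#' @return readCounts with appended rows; artefact loci are numbered after
#'   the existing loci and flagged with `is_artefact = TRUE`
#' @export
injectArtefacts <- function(readCounts, samples, proportions, nArtefacts) {
    stopifnot(nArtefacts >= 0)
    if (!"is_artefact" %in% names(readCounts))
        readCounts$is_artefact <- rep(FALSE, nrow(readCounts))
    if (nArtefacts == 0) return(readCounts)
    locus0 <- if (nrow(readCounts)) max(readCounts$locus) else 0L
    rows <- vector("list", nArtefacts * nrow(samples))
    k <- 0L
    for (a in seq_len(nArtefacts)) {
        for (s in seq_len(nrow(samples))) {
            mu <- samples$purity[s]
            gam <- samples$coverage[s]
            present <- which(proportions[, s] > 0)
            nc <- length(present)
            uA <- stats::rgamma(nc, 1); uA <- uA / sum(uA)
            carrier <- stats::runif(nc) < 0.5
            psi <- mu * sum(uA[carrier]) / (mu * 2 + 2 * (1 - mu)) * 1
            t <- stats::rpois(1L, gam)
            v <- stats::rbinom(1L, t, psi)
            k <- k + 1L
            rows[[k]] <- data.frame(
                locus = locus0 + a, sample_id = samples$sample_id[s],
                total_count = t, var_count = v, psi = psi,
                is_artefact = TRUE, stringsAsFactors = FALSE)
        }
    }
    rbind(readCounts, do.call(rbind, rows))
}
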