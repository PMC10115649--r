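test_that("clone proportions live on the simplex", {
    set.seed(10)
    ph1 <- simulateTopology(1)
    b1 <- sampleBulk(ph1, 2, purity = 0.5)
    expect_equal(unname(b1$proportions[1, ]), c(1, 1))   # single clone
    ph <- simulateTopology(10)
    b <- sampleBulk(ph, 50, purity = 0.7)
    expect_true(all(abs(colSums(b$proportions) - 1) < 1e-12))
    expect_error(sampleBulk(ph, 0, 0.5), "positive")
})

test_that("clones per sample are uniform on 3..8", {
    set.seed(11)
    ph <- simulateTopology(12)
    b <- sampleBulk(ph, 10000, purity = 0.5)
    nHat <- colSums(b$proportions > 0)
    expect_true(all(nHat %in% 3:8))
    p <- 1 / 6
    se <- sqrt(p * (1 - p) / 10000)
    for (k in 3:8)
        expect_lt(abs(mean(nHat == k) - p), 3 * se + 1e-12)
})

test_that("fractional copy number and ploidy follow the weighted-mean formulas", {
    ph <- makePhylo(c(1, 2), c(0, 1))
    ## all clones diploid
    g <- propagateGenotypes(ph, makeEvents(character(0), integer(0), phylo = ph),
                            nArms = 4)
    st <- computeSampleState(c(`1` = 0.5, `2` = 0.5), g)
    expect_equal(st$fArm, rep(2, 4))
    expect_equal(st$rho, 2)
    ## clone 2 gains 2 copies on arm 1: total CN 4 there, mixed 50/50 -> f=3
    ev <- makeEvents("GAIN", 2, arm = 1, allele = "A", magnitude = 2, phylo = ph)
    g2 <- propagateGenotypes(ph, ev, nArms = 2)
    st2 <- computeSampleState(c(`1` = 0.5, `2` = 0.5), g2)
    expect_equal(st2$fArm[1], 3)
    ## arm f values {4, 2} -> rho = 3 for the pure doubled clone
    ev3 <- makeEvents(c("GAIN", "GAIN"), c(2, 2), arm = 1, allele = c("A", "B"),
                      magnitude = 1, phylo = ph)
    st3 <- computeSampleState(c(`1` = 0, `2` = 1),
                              propagateGenotypes(ph, ev3, nArms = 2))
    expect_equal(st3$fArm, c(4, 2))
    expect_equal(st3$rho, 3)
})

test_that("read counts match their closed-form means", {
    set.seed(12)
    ph <- makePhylo(1, 0)
    ## single diploid clone with one heterozygous SNV, mu = 1
    ev <- makeEvents("SNV", 1, locus = 1, arm = 1, allele = "A", phylo = ph)
    g <- propagateGenotypes(ph, ev, nArms = 1)
    u <- c(`1` = 1)
    expect_equal(expectedVAF(u, g, purity = 1), 0.5)
    ## E[t] = (f / rho) * gamma = 400; Monte-Carlo at 1e5 draws
    n <- 1e5
    reads <- do.call(rbind, lapply(seq_len(n / 1000), function(i) {
        gg <- g
        gg$z <- g$z[rep(1, 1000), , drop = FALSE]
        gg$locusArm <- rep(1L, 1000)
        generateReads(u, gg, purity = 1, coverage = 400)
    }))
    expect_lt(abs(mean(reads$total_count) - 400), 3 * sqrt(400 / n))
    vaf <- reads$var_count / reads$total_count
    sdv <- stats::sd(vaf)
    expect_lt(abs(mean(vaf) - 0.5), 3 * sdv / sqrt(n))
    expect_true(all(reads$var_count <= reads$total_count))
    ## loci with z = 0 everywhere never yield variant reads
    ev0 <- makeEvents(character(0), integer(0), phylo = ph)
    g0 <- propagateGenotypes(ph, ev0, nArms = 1)
    g0$z <- matrix(0L, 50, 1, dimnames = list(NULL, "1"))
    g0$locusArm <- rep(1L, 50)
    r0 <- generateReads(u, g0, purity = 0.8, coverage = 100)
    expect_true(all(r0$psi == 0) && all(r0$var_count == 0))
})

test_that("normal contamination dilutes the expected VAF", {
    ph <- makePhylo(1, 0)
    ev <- makeEvents("SNV", 1, locus = 1, arm = 1, allele = "A", phylo = ph)
    g <- propagateGenotypes(ph, ev, nArms = 1)
    ## mu = 0.5: psi = 0.5 * 1 / (0.5 * 2 + 2 * 0.5) = 0.25
    expect_equal(expectedVAF(c(`1` = 1), g, purity = 0.5), 0.25)
})

test_that("artefact loci are appended with sample-independent signals", {
    set.seed(13)
    ph <- simulateTopology(6)
    b <- sampleBulk(ph, 4, purity = 0.6, coverage = 200)
    g <- propagateGenotypes(ph, makeEvents(character(0), integer(0), phylo = ph))
    rc <- data.frame(locus = integer(0), total_count = integer(0),
                     var_count = integer(0), psi = numeric(0),
                     sample_id = character(0))
    expect_identical(injectArtefacts(rc, b$samples, b$proportions, 0)$locus,
                     rc$locus)
    out <- injectArtefacts(rc, b$samples, b$proportions, 30)
    expect_equal(nrow(out), 30 * 4)
    expect_equal(length(unique(out$locus)), 30)
    expect_true(all(out$is_artefact))
    ## psi drawn independently per sample: artefact loci disagree across
    ## samples (no shared clone structure)
    psiBy <- tapply(out$psi, out$locus, function(x) max(x) - min(x))
    expect_gt(mean(psiBy > 1e-6), 0.8)
})
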