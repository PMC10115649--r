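test_that("mutational ITH is the subclonal fraction of classified mutations", {
    expect_equal(mutationalITH(rep("truncal", 10)), 0)
    expect_equal(mutationalITH(c(rep("subclonal", 40), rep("truncal", 60))), 0.4)
    expect_equal(mutationalITH(rep("subclonal", 5)), 1)
    ## removed mutations are excluded from both counts
    expect_equal(mutationalITH(c("truncal", "subclonal", "removed")), 0.5)
    expect_true(is.na(mutationalITH(character(0))))
})

test_that("SCNA ITH divides heterogeneous by any-aberrant genome", {
    st <- rbind(c("gain", "gain"), c("loss", "neutral"),
                c("neutral", "neutral"), c("gain", "loss"))
    len <- c(10, 10, 80, 10)
    ## aberrant: rows 1, 2, 4 (30); heterogeneous among them: rows 2, 4 (20)
    expect_equal(scnaITH(st, len), 2 / 3)
    ## identical profiles in all regions -> 0
    expect_equal(scnaITH(rbind(c("gain", "gain"), c("loss", "loss"))), 0)
    ## no SCNAs -> missing
    expect_true(is.na(scnaITH(matrix("neutral", 3, 2))))
    ## invariant under region relabelling
    expect_equal(scnaITH(st[, 2:1], len), scnaITH(st, len))
    ## 40% aberrant of which half discordant -> 0.5
    st2 <- rbind(c("gain", "gain"), c("gain", "neutral"),
                 c("neutral", "neutral"), c("neutral", "neutral"),
                 c("neutral", "neutral"))
    expect_equal(scnaITH(st2), 0.5)
})

test_that("wGII weights chromosomes equally and FLOH is the LOH fraction", {
    ## 22 chromosomes, one fully aberrant -> 1/22
    chrom <- rep(1:22, each = 2)
    len <- rep(c(60, 40), 22)
    cn <- rep(2, 44); cn[chrom == 5] <- 4
    expect_equal(wgii(chrom, len, cn, ploidy = 2), 1 / 22)
    expect_equal(wgii(chrom, len, rep(2, 44), 2), 0)
    ## splitting a segment while preserving states leaves wGII unchanged
    chrom2 <- c(chrom, 5, 5); len2 <- c(len, 0, 0)
    w1 <- wgii(chrom, len, cn, 2)
    chromS <- rep(1:22, each = 4); lenS <- rep(c(30, 30, 20, 20), 22)
    cnS <- rep(2, 88); cnS[chromS == 5] <- 4
    expect_equal(wgii(chromS, lenS, cnS, 2), w1)
    ## FLOH
    expect_equal(floh(c(50, 50), c(0, 1)), 0.5)
    expect_equal(floh(c(10, 10), c(0, 0)), 1)
    expect_equal(floh(c(10, 10), c(1, 2)), 0)
})

test_that("segment states follow the ploidy-relative thresholds", {
    expect_equal(segmentStates(c(1, 2, 3, 5), ploidy = 2),
                 c("loss", "neutral", "gain", "amp"))
    expect_equal(segmentStates(c(2, 4, 6, 9), ploidy = 4),
                 c("loss", "neutral", "gain", "amp"))
})

test_that("recent expansion score takes leaf maxima across regions", {
    ccf <- rbind(trunk = c(1, 1), B = c(0.5, 0.2), C = c(0.1, 0.7))
    tree <- buildCloneTree(ccf)
    ## leaves are B and C: regional leaf maxima 0.5 and 0.7 -> 0.7
    sc <- recentExpansionScore(tree)
    expect_equal(sc$score, 0.7)
    expect_lte(sc$min_over_alternatives, sc$score)
    ## a clonal leaf gives 1 after clipping
    ccf2 <- rbind(trunk = c(1, 1), B = c(1.05, 0.3))
    sc2 <- recentExpansionScore(buildCloneTree(ccf2))
    expect_equal(sc2$score, 1)
    ## chain vs star alternatives: min over alternatives can be lower
    ccf3 <- rbind(trunk = c(1, 1), B = c(0.8, 0.8), C = c(0.3, 0.3))
    sc3 <- recentExpansionScore(buildCloneTree(ccf3))
    ## star tree: leaves {B, C} -> 0.8; chain: leaf {C} -> 0.3
    expect_equal(sc3$min_over_alternatives, 0.3)
    expect_gte(sc3$score, sc3$min_over_alternatives)
})

test_that("SBS4 detection classes apply the printed thresholds verbatim", {
    expect_equal(classifySBS4(0.05, 30), "undetected")
    expect_equal(classifySBS4(0.35, 25), "high_confidence")
    expect_equal(classifySBS4(0.2, 100), "low_confidence")
    ## boundaries are strict inequalities
    expect_equal(classifySBS4(0.1, 10), "low_confidence")
    expect_equal(classifySBS4(0.3, 100), "low_confidence")
    expect_equal(classifySBS4(0.05, 50), "low_confidence")
    expect_equal(classifySBS4(0.5, 20), "low_confidence")
})
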