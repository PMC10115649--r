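chain3 <- function() makePhylo(c(1, 2), c(0, 1))   # germline -> 1 -> 2

test_that("no events leaves every clone diploid unmutated", {
    ph <- chain3()
    g <- propagateGenotypes(ph, makeEvents(character(0), integer(0), phylo = ph))
    expect_true(all(g$x == 1L) && all(g$y == 1L))
    expect_equal(nrow(g$z), 0L)
})

test_that("within-edge order matters: SNV/WGD permutations", {
    ph <- chain3()
    ## SNV then WGD -> (2,2,2)
    ev <- makeEvents(c("SNV", "WGD"), c(2, 2), locus = c(1, NA),
                     arm = c(1, NA), allele = c("A", NA), phylo = ph)
    g <- propagateGenotypes(ph, ev)
    expect_equal(unname(c(g$x[1, "2"], g$y[1, "2"], g$z[1, "2"])), c(2L, 2L, 2L))
    ## WGD then SNV -> (2,2,1)
    ev2 <- makeEvents(c("WGD", "SNV"), c(2, 2), locus = c(NA, 1),
                      arm = c(NA, 1), allele = c(NA, "A"), phylo = ph)
    g2 <- propagateGenotypes(ph, ev2)
    expect_equal(unname(c(g2$x[1, "2"], g2$y[1, "2"], g2$z[1, "2"])), c(2L, 2L, 1L))
    ## parent clone 1 untouched in both cases
    expect_equal(unname(g$z[1, "1"]), 0L)
})

test_that("LOH is irreversible and losses of mutant copies decrement z", {
    ph <- chain3()
    ## clone 1: SNV at locus 1 then lose B; clone 2: lose A (mutant, z=x),
    ## then a GAIN on the lost allele which must be skipped
    ev <- rbind(
        makeEvents(c("SNV", "LOSS"), c(1, 1), locus = c(1, NA),
                   arm = 1, allele = c("A", "B"), phylo = ph),
        makeEvents(c("LOSS", "GAIN"), c(2, 2), locus = NA, arm = 1,
                   allele = "A", magnitude = c(NA, 1), phylo = ph))
    g <- propagateGenotypes(ph, ev)
    expect_equal(unname(c(g$x[1, "1"], g$y[1, "1"], g$z[1, "1"])), c(1L, 0L, 1L))
    expect_equal(unname(c(g$x[1, "2"], g$y[1, "2"], g$z[1, "2"])), c(0L, 0L, 0L))
    expect_true(any(g$skipped$kind == "GAIN"))
    ## loss of a wild-type copy (z < x) keeps z
    ev2 <- makeEvents(c("SNV", "GAIN", "LOSS"), c(1, 1, 1),
                      locus = c(1, NA, NA), arm = 1, allele = "A",
                      magnitude = c(NA, 1, NA), phylo = ph)
    g2 <- propagateGenotypes(ph, ev2)
    ## SNV (1,1,1) -> gain duplicates the mutant copy (2,1,2) -> loss with
    ## z = x removes a mutant copy (1,1,1)
    expect_equal(unname(c(g2$x[1, "1"], g2$y[1, "1"], g2$z[1, "1"])), c(1L, 1L, 1L))
})

test_that("one WGD doubles any genotype exactly", {
    ph <- chain3()
    ## (1,1,0) doubles to (2,2,0)
    ev <- makeEvents("WGD", 1, phylo = ph)
    g <- propagateGenotypes(ph, ev)
    expect_true(all(g$x[, "1"] == 2L) && all(g$y[, "1"] == 2L))
    ## arbitrary prior state doubles component-wise
    ev2 <- rbind(
        makeEvents(c("SNV", "GAIN"), c(1, 1), locus = c(1, NA), arm = 1,
                   allele = "A", magnitude = c(NA, 2), phylo = ph),
        makeEvents("WGD", 2, phylo = ph))
    g2 <- propagateGenotypes(ph, ev2)
    expect_equal(unname(2L * c(g2$x[1, "1"], g2$y[1, "1"], g2$z[1, "1"])),
                 unname(c(g2$x[1, "2"], g2$y[1, "2"], g2$z[1, "2"])))
})

test_that("common allele-specific states are reachable with few events", {
    ## brute force over all sequences of at most 1 WGD, 2 gains, 2 losses
    ph <- chain3()
    states <- new.env()
    opts <- list(
        list(kind = "WGD", allele = NA, magnitude = NA),
        list(kind = "GAIN", allele = "A", magnitude = 1),
        list(kind = "GAIN", allele = "B", magnitude = 1),
        list(kind = "LOSS", allele = "A", magnitude = NA),
        list(kind = "LOSS", allele = "B", magnitude = NA))
    counts <- function(seq) c(sum(seq == 1), sum(seq %in% 2:3), sum(seq %in% 4:5))
    for (len in 0:5) {
        grid <- if (len) expand.grid(rep(list(1:5), len)) else data.frame()
        for (i in seq_len(max(nrow(grid), 1))) {
            sq <- if (len) as.integer(grid[i, ]) else integer(0)
            cn <- counts(sq)
            if (cn[1] > 1 || cn[2] > 2 || cn[3] > 2) next
            ev <- makeEvents(
                vapply(sq, function(k) opts[[k]]$kind, ""),
                rep(1, length(sq)), locus = NA, arm = 1,
                allele = vapply(sq, function(k) as.character(opts[[k]]$allele), ""),
                magnitude = vapply(sq, function(k) as.numeric(opts[[k]]$magnitude), 1),
                phylo = ph)
            g <- propagateGenotypes(ph, ev)
            key <- paste(max(g$x[1, "1"], g$y[1, "1"]),
                         min(g$x[1, "1"], g$y[1, "1"]))
            assign(key, TRUE, envir = states)
        }
    }
    reached <- ls(states)
    for (want in c("2 1", "3 1", "4 1", "3 2", "4 2", "1 0", "2 0"))
        expect_true(want %in% reached, label = paste("state", want))
})
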