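test_that("per-region WGD counting applies the 50% major-CN rules", {
    expect_equal(countWGDPerRegion(rep(1, 10)), 0L)
    expect_equal(countWGDPerRegion(c(2, 2, 1), c(60, 0, 40)), 1L)
    expect_equal(countWGDPerRegion(c(3, 1), c(55, 45)), 2L)
    expect_equal(countWGDPerRegion(c(2, 1), c(50, 50)), 1L)   # >= 0.5 inclusive
    expect_equal(countWGDPerRegion(c(4, 1), c(49, 51)), 0L)
    expect_true(is.na(countWGDPerRegion(numeric(0))))
})

test_that("doubled fractions respect the expected-major-CN eligibility", {
    expect_equal(doubledFraction(c(2, 2, 2, 2, 1, 1, 1, 1, 1, 1),
                                 rep(2, 10), 1), 0.4)
    ## member on an amplified segment (major 3 with one WGD) is excluded
    expect_equal(doubledFraction(c(2, 2, 1), c(2, 3, 2), 1), 0.5)
    expect_true(is.na(doubledFraction(c(2, 2), c(3, 3), 1)))
    ## doubled means mutCN > 1.5 strictly
    expect_equal(doubledFraction(c(1.5, 1.51), c(1, 1), 0), 0.5)
})

test_that("genome-doubled clusters use 0.25 then 0.1 thresholds inclusively", {
    fr <- rbind(A = c(R1 = 0.30, R2 = 0.15),
                B = c(R1 = 0.20, R2 = 0.20),
                C = c(R1 = 0.25, R2 = 0.05))
    fl <- flagGDClusters(fr)
    expect_equal(fl$doubled, c(TRUE, FALSE, TRUE))
    expect_equal(fl$regions[fl$cluster == "A"], "R1,R2")
    expect_equal(fl$regions[fl$cluster == "C"], "R1")
})

test_that("doubled clusters merge by region set into distinct events", {
    counts <- c(R1 = 1L, R2 = 1L)
    meta <- data.frame(cluster = c("A", "B"), is_trunk = FALSE,
                       mean_ccf = c(0.5, 0.4))
    ## same regions -> one event
    fl <- data.frame(cluster = c("A", "B"), doubled = TRUE,
                     regions = "R1,R2")
    ev <- inferWGDEvents(fl, counts, meta)
    expect_equal(nrow(wgdEvents(ev)), 1L)
    expect_equal(wgdEvents(ev)$clonality, "subclonal")
    expect_equal(wgdEvents(ev)$regions, "R1,R2")
    ## different regions -> two parallel events
    fl2 <- data.frame(cluster = c("A", "B"), doubled = TRUE,
                      regions = c("R1", "R2"))
    ev2 <- inferWGDEvents(fl2, counts, meta)
    expect_equal(nrow(wgdEvents(ev2)), 2L)
    expect_true(all(wgdEvents(ev2)$clonality == "subclonal"))
    expect_setequal(wgdEvents(ev2)$regions, c("R1", "R2"))
    expect_error(inferWGDEvents(
        data.frame(cluster = "A", doubled = TRUE, regions = "R9"),
        counts, meta), "unknown region")
})

test_that("parsimony fallback shares region-count WGDs where possible", {
    noFlags <- data.frame(cluster = character(0), doubled = logical(0),
                          regions = character(0))
    meta0 <- data.frame(cluster = character(0), is_trunk = logical(0),
                        mean_ccf = numeric(0))
    ev <- inferWGDEvents(noFlags, c(R1 = 1L, R2 = 1L, R3 = 1L), meta0)
    expect_equal(nrow(wgdEvents(ev)), 1L)
    expect_equal(wgdEvents(ev)$clonality, "truncal")
    expect_equal(ev@status, "truncal_only")
    ev2 <- inferWGDEvents(noFlags, c(R1 = 2L, R2 = 1L, R3 = 0L), meta0)
    e <- wgdEvents(ev2)
    expect_equal(nrow(e), 2L)
    expect_setequal(e$regions, c("R1,R2", "R1"))
    expect_true(all(e$clonality == "subclonal"))
    ev0 <- inferWGDEvents(noFlags, c(R1 = 0L, R2 = 0L), meta0)
    expect_equal(ev0@status, "no_wgd")
})

test_that("region capacity caps assigned events and subclonal count caps at 2", {
    counts <- c(R1 = 1L, R2 = 1L)
    meta <- data.frame(cluster = c("A", "B", "C", "trunk"),
                       is_trunk = c(FALSE, FALSE, FALSE, TRUE),
                       mean_ccf = c(0.3, 0.5, 0.7, 2))
    fl <- data.frame(cluster = c("A", "B", "C", "trunk"), doubled = TRUE,
                     regions = c("R1", "R2", "R1,R2", "R1,R2"))
    ev <- inferWGDEvents(fl, counts, meta)
    e <- wgdEvents(ev)
    ## validity enforces the per-region cap; deepest clusters won the slots
    expect_true(validObject(ev))
    expect_lte(sum(e$clonality == "subclonal"), 2L)
    used <- table(unlist(strsplit(e$regions, ",")))
    expect_true(all(used <= counts[names(used)]))
    ## excess subclonal events trigger the review flag after merging
    counts3 <- c(R1 = 2L, R2 = 2L, R3 = 2L)
    fl3 <- data.frame(cluster = c("A", "B", "C"), doubled = TRUE,
                      regions = c("R1", "R2", "R3"))
    meta3 <- meta[1:3, ]
    ev3 <- inferWGDEvents(fl3, counts3, meta3)
    expect_lte(sum(wgdEvents(ev3)$clonality == "subclonal"), 2L)
    expect_true(ev3@reviewFlag)
})

test_that("tumour-level WGD status summarises the event set", {
    e0 <- data.frame(event_id = character(0), clonality = character(0),
                     regions = character(0), source = character(0),
                     clusters = character(0))
    expect_equal(tumourWGDStatus(e0), "no_wgd")
    expect_equal(tumourWGDStatus(data.frame(clonality = "truncal")),
                 "truncal_only")
    expect_equal(tumourWGDStatus(data.frame(clonality = c("truncal",
                                                          "subclonal"))),
                 "subclonal")
})

test_that("same-ploidy parallel WGDs on sibling clones yield two events", {
    ## germline -> 1 (MRCA); 1 -> 2 and 1 -> 3; each sibling doubles and
    ## sweeps its own region, so both regions reach ploidy ~4 and the
    ## per-region counts (1, 1) look like a shared truncal doubling
    ph <- makePhylo(c(1, 2, 3), c(0, 1, 1))
    ev <- rbind(
        makeEvents("SNV", rep(1, 10), locus = 1:10,
                   arm = rep(1:2, 5), allele = "A", phylo = ph),
        makeEvents(c(rep("SNV", 8), "WGD"), rep(2, 9),
                   locus = c(11:18, NA), arm = c(rep(3, 8), NA),
                   allele = c(rep("A", 8), NA), phylo = ph),
        makeEvents(c(rep("SNV", 8), "WGD"), rep(3, 9),
                   locus = c(19:26, NA), arm = c(rep(4, 8), NA),
                   allele = c(rep("A", 8), NA), phylo = ph))
    U <- matrix(c(0, 1, 0, 0, 0, 1), 3, 2,
                dimnames = list(1:3, c("R1", "R2")))
    tum <- makeManualTumour(ph, ev, U, purity = 1, coverage = 400)
    b <- benchmarkTumour(tum, noiseless = TRUE)
    expect_equal(unname(b$region_counts), c(1L, 1L))
    e <- wgdEvents(b$events)
    expect_equal(sum(e$clonality == "subclonal"), 2L)
    expect_setequal(e$regions[e$clonality == "subclonal"], c("R1", "R2"))
    ## the region-count baselines cannot see these parallel events
    expect_false(baselineNEJM(b$region_counts)$nejm_subclonal)
    expect_equal(baselineNEJM(b$region_counts)$nejm2_n_subclonal, 0L)
    expect_true(b$call_parallelgd && !b$call_nejm2)
})

test_that("noiseless detection matches truth for clean sweeps", {
    ## truncal WGD only
    ph <- makePhylo(c(1, 2), c(0, 1))
    ev <- rbind(
        makeEvents(c(rep("SNV", 10), "WGD"), rep(1, 11),
                   locus = c(1:10, NA), arm = c(rep(1, 10), NA),
                   allele = c(rep("A", 10), NA), phylo = ph),
        makeEvents("SNV", rep(2, 6), locus = 11:16, arm = 2, allele = "A",
                   phylo = ph))
    U <- matrix(c(0.5, 0.5, 1, 0), 2, 2, dimnames = list(1:2, c("R1", "R2")))
    tum <- makeManualTumour(ph, ev, U)
    b <- benchmarkTumour(tum, noiseless = TRUE)
    e <- wgdEvents(b$events)
    expect_equal(e$clonality, "truncal")
    expect_equal(e$regions, "R1,R2")
    expect_equal(b$events@status, "truncal_only")
    ## nested subclonal WGDs: chain 1 -> 2 -> 3, WGD on 2 and on 3
    ph2 <- makePhylo(c(1, 2, 3), c(0, 1, 2))
    ev2 <- rbind(
        makeEvents("SNV", rep(1, 10), locus = 1:10, arm = 1, allele = "A",
                   phylo = ph2),
        makeEvents(c(rep("SNV", 6), "WGD"), rep(2, 7),
                   locus = c(11:16, NA), arm = c(rep(2, 6), NA),
                   allele = c(rep("A", 6), NA), phylo = ph2),
        makeEvents(c(rep("SNV", 6), "WGD"), rep(3, 7),
                   locus = c(17:22, NA), arm = c(rep(3, 6), NA),
                   allele = c(rep("A", 6), NA), phylo = ph2))
    U2 <- matrix(c(0, 0, 1, 0, 1, 0), 3, 2,
                 dimnames = list(1:3, c("R1", "R2")))
    tum2 <- makeManualTumour(ph2, ev2, U2)
    b2 <- benchmarkTumour(tum2, noiseless = TRUE)
    expect_equal(unname(b2$region_counts), c(2L, 1L))
    e2 <- wgdEvents(b2$events)
    expect_equal(sum(e2$clonality == "subclonal"), 2L)
    expect_setequal(e2$regions, c("R1", "R1,R2"))
})
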