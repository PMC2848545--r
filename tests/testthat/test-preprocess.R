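test_that("background replicates are median-normalized then median-combined", {
    # one replicate with grand median 2: every value halved
    one <- matrix(c(1, 2, 4), 3)
    expect_equal(combineBackground(one), c(0.5, 1, 2))
    # identical replicates: result equals any one normalized replicate
    three <- cbind(c(1, 2, 4), c(1, 2, 4), c(1, 2, 4))
    expect_equal(combineBackground(three), c(0.5, 1, 2))
    # per-probe median across normalized replicates
    reps <- rbind(c(1, 2, 3), c(10, 10, 10), c(0.1, 0.2, 0.15))
    normed <- sweep(reps, 2, apply(reps, 2, median), "/")
    expect_equal(combineBackground(reps)[1], median(normed[1, ]))
    expect_error(combineBackground(matrix(c(-1, 2), 1)), "positive")
})

test_that("fold over background centers the T-T median at exactly 1", {
    set.seed(41)
    bg <- runif(200, 0.5, 2)
    sig <- bg * runif(200, 0.8, 6)
    tt <- 151:200
    fold <- foldOverBackground(sig, bg, tt)
    expect_identical(median(fold[tt]), 1)
    # signal == background everywhere: all folds 1
    expect_equal(foldOverBackground(bg, bg, tt), rep(1, 200))
    # doubling one probe's signal doubles its fold only
    sig2 <- sig; sig2[3] <- 2 * sig[3]
    fold2 <- foldOverBackground(sig2, bg, tt)
    expect_equal(fold2[3], 2 * fold[3])
    expect_equal(fold2[-3], fold[-3])
    expect_error(foldOverBackground(sig, bg, integer(0)), "T-T")
})

test_that("percent scaling anchors background at 0% and the 99th percentile\n          at 100%", {
    folds <- c(seq(1, 4.96, length.out = 99), 5, 6)   # p99 anchor = 5
    pct <- scalePercent(folds)
    expect_identical(pct[1], 0)                # fold 1 -> 0%
    expect_identical(pct[100], 100)            # fold = p99 -> 100%
    expect_identical(pct[101], 100)            # clamp above the anchor
    expect_equal(scalePercent(c(folds, 3))[102], 50)  # (3-1)/(5-1)
    # sub-background folds are clamped at 0
    expect_identical(scalePercent(c(folds, 0.5))[102], 0)
    # monotone non-decreasing in fold
    expect_true(all(diff(scalePercent(sort(folds))) >= 0))
    expect_error(scalePercent(rep(0.9, 100)), "degenerate")
})

test_that("percent scaling is idempotent on re-expressed folds", {
    set.seed(42)
    folds <- c(runif(500, 0.8, 8), 9, 9.5)
    pct <- scalePercent(folds)
    p <- sort(folds)[ceiling(0.99 * length(folds))]
    refolded <- 1 + pct / 100 * (p - 1)
    expect_equal(scalePercent(refolded), pct, tolerance = 1e-10)
})

test_that("H/L assignment sends exact-cutoff values to H and builds all\n          2^n labels", {
    tab <- OccupancyTable(rbind(c(9.99, 10), c(40, 5)), "TB")
    expect_identical(assignGroups(tab), c("(L,H)", "(H,L)"))
    expect_identical(assignGroups(tab, cutoff = 15), c("(L,L)", "(H,L)"))
    arch3 <- archTable("TBP")
    expect_identical(sort(unique(assignGroups(arch3))),
                     sort(rownames(occupancies(arch3))))
    zeros <- OccupancyTable(matrix(0, 5, 3), "TBP")
    expect_identical(unique(assignGroups(zeros)), "(L,L,L)")
})

test_that("consolidation keeps well-supported splits and merges weak ones\n          under the larger child's label", {
    mk <- function(sizes, labels) rep(labels, sizes)
    # 150/120: both exempt (> 100), kept
    parent <- mk(c(270), "(H)")
    child <- mk(c(150, 120), c("(H,L)", "(H,H)"))
    expect_identical(consolidateGroups(parent, child), child)
    # 95/8: child below 10, merged into the 95-member child's label
    parent <- mk(c(103), "(H)")
    child <- mk(c(95, 8), c("(H,L)", "(H,H)"))
    out <- consolidateGroups(parent, child)
    expect_identical(unique(out), "(H,L)")
    expect_length(out, 103)                     # membership conserved
    # 80/15: ratio > 4:1 and neither exempt, merged
    parent <- mk(c(95), "(L)")
    child <- mk(c(80, 15), c("(L,H)", "(L,L)"))
    expect_identical(unique(consolidateGroups(parent, child)), "(L,H)")
    # 40/15: ratio <= 4:1 and both >= 10, kept
    parent <- mk(c(55), "(L)")
    child <- mk(c(40, 15), c("(L,H)", "(L,L)"))
    expect_identical(consolidateGroups(parent, child), child)
    # merged group is never smaller than the smaller child
    expect_gte(sum(consolidateGroups(mk(103, "(H)"),
                                     mk(c(95, 8), c("a", "b"))) == "a"), 95)
    expect_error(consolidateGroups(c("(H)", "(L)"), c("x", "x")), "refine")
})

test_that("group medians are per-factor medians and valid chart input", {
    tab <- OccupancyTable(rbind(c(10, 50), c(20, 60), c(90, 70),
                                c(5, 5)), "TB")
    med <- groupMedians(tab, c("g1", "g1", "g1", "g2"))
    expect_equal(unname(occupancies(med)["g1", ]), c(20, 60))
    expect_equal(unname(occupancies(med)["g2", ]), c(5, 5))  # singleton
    expect_identical(attr(occupancies(med), "membership"), c(3L, 1L))
    expect_s4_class(compatibilityMatrix("TB", med), "CompatibilityMatrix")
})

test_that("medians of L-labeled groups stay below the cutoff", {
    cfg <- testProbeConfig(seed = 2)
    occ <- occupancyFromProbes(generateProbeDataset(cfg), "TBP")
    labels <- assignGroups(occ)
    med <- occupancies(groupMedians(occ, labels))
    for (g in rownames(med)) {
        letters <- strsplit(gsub("[()]", "", g), ",")[[1]]
        expect_true(all(med[g, letters == "L"] < 10))
    }
})

test_that("incremental grouping consolidates only beyond three factors", {
    set.seed(43)
    # four factors; make the 4th factor split one group 95/8 and another 150/120
    n <- 4
    occ <- matrix(5, 500, n)
    occ[1:270, 1] <- 40                      # (H,...) parent of 270
    occ[271:373, 2] <- 40                    # (L,H,..) parent of 103
    occ[1:150, 4] <- 40                      # 150/120 split: kept
    occ[271:278, 4] <- 40                    # 8/95 split: merged
    tab <- OccupancyTable(occ, "TBPF")
    lab <- groupOccupancies(tab)
    expect_true(all(c("(H,L,L,H)", "(H,L,L,L)") %in% lab))   # kept split
    expect_identical(sum(lab == "(L,H,L,H)"), 0L)            # merged away
    expect_identical(sum(lab == "(L,H,L,L)"), 103L)
    expect_identical(groupOccupancies(tab, consolidate = FALSE),
                     assignGroups(tab))
    # n = 3: no consolidation even with tiny groups
    tab3 <- OccupancyTable(occ[, 1:3], "TBP")
    expect_identical(groupOccupancies(tab3), assignGroups(tab3))
    expect_identical(sum(table(lab)), 500L)                  # conservation
})

test_that("cutoff variants do not change the chart rows of large groups", {
    cfg <- testProbeConfig(seed = 4)
    occ <- occupancyFromProbes(generateProbeDataset(cfg), "TBP")
    for (cut in c(15)) {
        lab10 <- assignGroups(occ, cutoff = 10)
        labV <- assignGroups(occ, cutoff = cut)
        m10 <- compatibilityMatrix("TBP", groupMedians(occ, lab10))
        mV <- compatibilityMatrix("TBP", groupMedians(occ, labV))
        big <- names(which(table(lab10) > 100))
        shared <- intersect(big, rownames(compatibilityCalls(mV)))
        expect_gt(length(shared), 0)
        expect_identical(compatibilityCalls(m10)[shared, , drop = FALSE],
                         compatibilityCalls(mV)[shared, , drop = FALSE])
    }
})
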