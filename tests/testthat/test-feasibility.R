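# The oracle's verdicts are verified against self-certifying evidence:
# a returned dwell assignment proves feasibility by direct substitution, a
# returned Farkas vector proves infeasibility by direct arithmetic.

checkWitness <- function(res, cyc, occ) {
    codes <- cyc@mechanism@association@codes
    if (res@feasible) {
        f <- res@dwell
        expect_true(all(f >= -1e-9))
        for (i in codes) {
            inState <- vapply(occupiedStates(cyc), function(s) i %in% s, TRUE)
            expect_equal(sum(f[inState]), unname(occ[i]), tolerance = 1e-6)
        }
    } else {
        y <- res@certificate
        expect_false(is.null(y))
        expect_gt(sum(y * occ[codes]), 0)
        for (s in occupiedStates(cyc))
            expect_lte(sum(y[codes %in% s]), 1e-9)
    }
}

test_that("two-factor nested cycle forces occ(B) <= occ(T)", {
    cyc <- buildStateCycle(mechanism("TB", dissociation = "BT"))
    bad <- lpFeasible(cyc, c(T = 30, B = 60))
    expect_false(bad@feasible)
    checkWitness(bad, cyc, c(T = 30, B = 60))
    good <- lpFeasible(cyc, c(T = 60, B = 30))
    expect_true(good@feasible)
    checkWitness(good, cyc, c(T = 60, B = 30))
})

test_that("three-factor middle-dominant vector is infeasible until the\n          middle occupancy drops below the neighbour sum", {
    cyc <- buildStateCycle(mechanism("TBP", dissociation = "TBP"))
    res1 <- lpFeasible(cyc, c(T = 20, B = 70, P = 30))
    expect_false(res1@feasible)
    checkWitness(res1, cyc, c(T = 20, B = 70, P = 30))
    res2 <- lpFeasible(cyc, c(T = 20, B = 45, P = 30))
    expect_true(res2@feasible)
    checkWitness(res2, cyc, c(T = 20, B = 45, P = 30))
})

test_that("degenerate cycle with no occupied states rejects any nonzero\n          occupancy with residual sum(occ^2)", {
    mech <- mechanism("T", dissociation = "T")
    degen <- new("StateCycle", states = list(character(0)),
                 occupiedStates = list(), mechanism = mech)
    res <- lpFeasible(degen, c(T = 30))
    expect_false(res@feasible)
    expect_equal(res@residual, 900)
    expect_true(lpFeasible(degen, c(T = 0))@feasible)
})

test_that("feasibility is scale invariant without the DNA-total cap", {
    mechs <- enumerateDissociations("TBP")
    vecs <- randomOccVectors(15, "TBP", seed = 21)
    for (r in seq_len(nrow(vecs))) {
        occ <- vecs[r, ]
        for (m in mechs[c(1, 4, 6)]) {
            cyc <- buildStateCycle(m)
            base <- lpFeasible(cyc, occ)@feasible
            for (lam in c(0.25, 0.8))
                expect_identical(lpFeasible(cyc, occ * lam)@feasible, base)
        }
    }
})

test_that("a cycle with a superset of occupied states can only gain\n          feasibility", {
    # LIFO occupied states (nested chain) are a subset of every other
    # mechanism's occupied states that extend the chain
    codes <- "TBP"
    lifo <- buildStateCycle(mechanism(codes, dissociation = "PBT"))
    fifo <- buildStateCycle(mechanism(codes, dissociation = "TBP"))
    lifoKeys <- vapply(occupiedStates(lifo), paste, "", collapse = "")
    fifoKeys <- vapply(occupiedStates(fifo), paste, "", collapse = "")
    expect_true(all(lifoKeys %in% fifoKeys))
    vecs <- randomOccVectors(30, codes, seed = 22)
    for (r in seq_len(nrow(vecs))) {
        occ <- vecs[r, ]
        if (lpFeasible(lifo, occ)@feasible)
            expect_true(lpFeasible(fifo, occ)@feasible)
    }
})

test_that("capTotal only matters when occupancies cannot share states", {
    cyc <- buildStateCycle(mechanism("TBP", dissociation = "TBP"))
    # disjoint-heavy demand: T and P both near 100, B near 0 -> total > 100
    occ <- c(T = 95, B = 2, P = 95)
    expect_true(lpFeasible(cyc, occ, capTotal = FALSE)@feasible)
    expect_false(lpFeasible(cyc, occ, capTotal = TRUE)@feasible)
    # archetype values are unaffected by the cap
    tabs <- occupancies(archTable("TBP"))
    for (r in seq_len(nrow(tabs)))
        expect_identical(lpFeasible(cyc, tabs[r, ], capTotal = TRUE)@feasible,
                         lpFeasible(cyc, tabs[r, ], capTotal = FALSE)@feasible)
})

test_that("oracle matrix reproduces the two-factor rejection and the\n          all-zero acceptance", {
    tab <- OccupancyTable(rbind(`(L,H)` = c(5, 40), `(H,H)` = c(40, 60)), "TB")
    om <- compatibilityCalls(oracleMatrix("TB", tab))
    expect_identical(unname(om[, "2"]), c(0L, 0L))   # B leaves first: rejected
    expect_identical(unname(om[, "1"]), c(-1L, -1L))
    zeros <- OccupancyTable(matrix(0, 2, 3), "TBP")
    expect_true(all(compatibilityCalls(oracleMatrix("TBP", zeros)) == -1L))
})

test_that("rules and oracle agree exactly on the three-factor archetype\n          chart", {
    tab <- archTable("TBP")
    expect_identical(compatibilityCalls(compatibilityMatrix("TBP", tab)),
                     compatibilityCalls(oracleMatrix("TBP", tab)))
})
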