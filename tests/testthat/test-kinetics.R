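test_that("model construction yields 2n irreversible reactions over the\n          cycle's distinct states", {
    m2 <- buildKineticModel(mechanism("TB", dissociation = "BT"))
    expect_identical(nrow(m2@reactions), 4L)
    expect_identical(length(m2@states), 3L)   # empty, T, TB
    m2b <- buildKineticModel(mechanism("TB", dissociation = "TB"))
    expect_identical(length(m2b@states), 4L)  # empty, T, TB, B
    m3 <- buildKineticModel(mechanism("TBP", id = 4))
    expect_identical(nrow(m3@reactions), 6L)
    expect_identical(sum(m3@reactions$type == "association"), 3L)
    expect_identical(sum(m3@reactions$type == "dissociation"), 3L)
})

test_that("steady state matches an independent full-species integration and\n          conserves mass", {
    set.seed(31)
    for (mech in list(mechanism("TB", dissociation = "TB"),
                      mechanism("TBP", dissociation = "BPT"))) {
        model <- buildKineticModel(mech)
        rates <- 10^runif(nrow(model@reactions), -1, 1)
        ss <- simulateSteadyState(model, rates)
        ref <- referenceSteadyState(model, rates)
        expect_equal(unname(ss$free), unname(ref$free), tolerance = 1e-5)
        expect_equal(unname(ss$states), unname(ref$states), tolerance = 1e-5)
        expect_equal(sum(ss$states), model@dnaTotal, tolerance = 1e-8)
        # per-factor conservation: free + bound = total
        codes <- factorCodes(mech)
        for (i in seq_along(codes)) {
            bound <- sum(ss$states[vapply(model@states, function(s)
                codes[i] %in% s, TRUE)])
            expect_equal(ss$free[[codes[i]]] + bound, model@proteinTotal,
                         tolerance = 1e-8)
        }
    }
})

test_that("equal rates give a positive symmetric dwell across the cycle and\n          a dominant dissociation rate empties its substrate state", {
    model <- buildKineticModel(mechanism("TB", dissociation = "TB"))
    ss <- simulateSteadyState(model, rates = rep(1, 4))
    expect_true(all(ss$states > 0))
    # the 4 distinct states form one cycle, so all steady fluxes are equal;
    # with equal rates the two unimolecular substrates (TB and B) must hold
    # equal concentrations v/k
    expect_equal(ss$states[["TB"]], ss$states[["B"]], tolerance = 1e-8)
    fluxes <- c(ss$states[["0"]] * ss$free[["T"]],
                ss$states[["T"]] * ss$free[["B"]],
                ss$states[["TB"]], ss$states[["B"]])
    expect_lt(diff(range(fluxes)), 1e-7 * max(fluxes))
    # crank one dissociation far up: its substrate state drains
    fast <- simulateSteadyState(model, rates = c(1, 1, 1e4, 1))
    expect_lt(fast$states[["TB"]], 1e-2)
    expect_error(simulateSteadyState(model, rates = c(1, 1)), "positive rate")
})

test_that("evalue implements the weighted squared error on the free-protein\n          scale with the 0.1% floor", {
    expect_identical(evalue(c(T = 30, B = 60), c(T = 30, B = 60)), 0)
    # single factor, simulated off by 20% occupancy = 2 concentration units
    expect_equal(evalue(c(T = 50), c(T = 70)), 4)
    e1 <- evalue(c(T = 10, B = 80), c(T = 20, B = 50))
    expect_equal(evalue(c(T = 10, B = 80), c(T = 20, B = 50), weights = 2),
                 2 * e1)
    # the floor: observed 0 is treated as 0.1%
    expect_equal(evalue(c(T = 0), c(T = 0.1)), 0)
    expect_error(evalue(c(T = 1), c(B = 1)), "same factor codes")
})

test_that("fits are deterministic under a fixed seed and separate compatible\n          from incompatible mechanisms", {
    occ <- c(T = 30, B = 60)
    fitA <- estimateParameters(mechanism("TB", id = 1), occ, nRestarts = 5,
                               seed = 42)
    fitA2 <- estimateParameters(mechanism("TB", id = 1), occ, nRestarts = 5,
                                seed = 42)
    expect_identical(fitA@E, fitA2@E)
    expect_identical(fitA@rates, fitA2@rates)
    expect_lt(fitA@log10E, defaultLog10EThreshold())
    expect_equal(unname(fitA@simulatedOcc), unname(occ), tolerance = 0.05)
    # the LP-infeasible pairing stays bounded away from zero on every seed
    for (s in c(1, 7)) {
        fitB <- estimateParameters(mechanism("TB", id = 2), occ,
                                   nRestarts = 5, seed = s)
        expect_gt(fitB@log10E, defaultLog10EThreshold() + 1)
    }
})

test_that("occupancies at the 0.1% floor are fit with near-zero E by every\n          mechanism", {
    occ <- c(T = 0, B = 0)
    for (id in 1:2) {
        fit <- estimateParameters(mechanism("TB", id = id), occ,
                                  nRestarts = 5, seed = 3)
        expect_lt(fit@log10E, defaultLog10EThreshold())
    }
})

test_that("reducing the DNA concentration to 1 leaves the classification\n          unchanged", {
    occ <- c(T = 30, B = 60)
    fit1 <- estimateParameters(mechanism("TB", id = 1), occ, nRestarts = 5,
                               seed = 5, dnaTotal = 1)
    fit2 <- estimateParameters(mechanism("TB", id = 2), occ, nRestarts = 5,
                               seed = 5, dnaTotal = 1)
    expect_true(classifyByEvalue(list(fit1))[1])
    expect_false(classifyByEvalue(list(fit2))[1])
})

test_that("classification helpers behave on simple inputs", {
    expect_identical(classifyByEvalue(c(-8, -6, 1), thresholdLog10E = -2),
                     c(TRUE, TRUE, FALSE))
    expect_identical(classifyByEvalue(c(-12, -12)), c(TRUE, TRUE))
    thr <- gapThreshold(c(-9, -8.5, -7, 0.5, 0.9, 1.2))
    expect_gt(thr, -7); expect_lt(thr, 0.5)
})
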